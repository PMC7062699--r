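#' nutrispec: leaf N/P/K estimation from hyperspectral reflectance
#'
#' Tools for building exhaustive two-band spectral indices from leaf
#' reflectance spectra (350--1000 nm, 1 nm resolution), correlating them
#' with leaf nitrogen, phosphorus and potassium content, selecting
#' sensitive wavelengths, fitting stepwise linear models, and comparing
#' against published empirical vegetation indices.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a spectra set
#'
#' The central container of the package: a collection of per-sample
#' spectra on one common integer-nanometre wavelength grid, optionally
#' carrying sample metadata (species, degradation intensity, replicate)
#' and a nutrient table (leaf N, P, K in mg per g dry matter).
#'
#' The wavelength grid must be strictly increasing, contiguous at 1 nm
#' steps. Reflectance values outside [0, 1] are kept but reported with a
#' warning: leaf-clip artifacts occur in real field data and silently
#' dropping them would change every band-pair scan downstream.
#'
#' @param values numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths integer vector of wavelengths (nm), one per column.
#' @param sample_ids character vector of unique sample identifiers.
#' @param meta optional data.frame with columns `sample_id`, `species`,
#'   `degradation` (one of `"light"`, `"moderate"`, `"severe"`) and
#'   `replicate`.
#' @param nutrients optional data.frame with columns `sample_id`, `N`,
#'   `P`, `K` (mg g-1 dry matter, strictly positive).
#' @param kind `"reflectance"` (dimensionless) or `"derivative"`
#'   (nm^-1, the forward-difference first derivative).
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(values, wavelengths, sample_ids = rownames(values),
                        meta = NULL, nutrients = NULL,
                        kind = c("reflectance", "derivative")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  wavelengths <- as.integer(round(wavelengths))
  if (ncol(values) != length(wavelengths))
    stop("values has ", ncol(values), " columns but ", length(wavelengths),
         " wavelengths were given")
  check_grid(wavelengths)
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite spectral values present")
  if (kind == "reflectance" && any(values < 0 | values > 1)) {
    n_bad <- sum(values < 0 | values > 1)
    warning(n_bad, " reflectance value(s) outside [0, 1] retained ",
            "(possible instrument artifact)")
  }
  dimnames(values) <- list(sample_ids, as.character(wavelengths))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    stopifnot(all(c("sample_id", "species", "degradation", "replicate")
                  %in% names(meta)))
    bad <- setdiff(unique(as.character(meta$degradation)),
                   c("light", "moderate", "severe"))
    if (length(bad))
      stop("unknown degradation level(s): ", paste(bad, collapse = ", "))
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id))
      stop("meta is missing rows for some sample_ids")
    rownames(meta) <- NULL
  }
  if (!is.null(nutrients)) {
    nutrients <- as.data.frame(nutrients)
    stopifnot(all(c("sample_id", "N", "P", "K") %in% names(nutrients)))
    nutrients <- nutrients[match(sample_ids, nutrients$sample_id), ,
                           drop = FALSE]
    if (anyNA(nutrients$sample_id))
      stop("nutrient table is missing rows for some sample_ids")
    vals <- as.matrix(nutrients[, c("N", "P", "K")])
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("nutrient values must be strictly positive and finite")
    rownames(nutrients) <- NULL
  }
  structure(
    list(wavelengths = wavelengths, values = values, kind = kind,
         meta = meta, nutrients = nutrients),
    class = "spectra_set")
}

# grid invariant: strictly increasing, contiguous, 1 nm step
check_grid <- function(wavelengths) {
  if (length(wavelengths) < 1L) stop("empty wavelength grid")
  d <- diff(wavelengths)
  if (any(d <= 0L)) stop("wavelength grid is not strictly increasing")
  if (any(d != 1L)) {
    at <- wavelengths[which(d != 1L)[1]] + 1L
    stop("grid gap at ", at)
  }
  invisible(wavelengths)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", n_samples(x), " sample(s), ",
      length(x$wavelengths), " bands (", min(x$wavelengths), "-",
      max(x$wavelengths), " nm), kind = ", x$kind, "\n", sep = "")
  if (!is.null(x$meta))
    cat("  meta: species x degradation x replicate attached\n")
  if (!is.null(x$nutrients))
    cat("  nutrients: N, P, K (mg g-1) attached\n")
  invisible(x)
}

#' Number of samples in a spectra set
#' @param x a `spectra_set`.
#' @return integer count of samples.
#' @export
n_samples <- function(x) nrow(x$values)

#' Sample identifiers of a spectra set
#' @param x a `spectra_set`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Wavelength grid of a spectra set
#' @param x a `spectra_set`.
#' @return integer vector of wavelengths (nm).
#' @export
wavelengths <- function(x) x$wavelengths

#' Subset a spectra set by sample id
#' @param x a `spectra_set`.
#' @param ids character vector of sample ids to keep (order preserved).
#' @return a `spectra_set` restricted to `ids`.
#' @export
subset_samples <- function(x, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  keep <- function(df) if (is.null(df)) NULL else
    df[match(ids, df$sample_id), , drop = FALSE]
  out <- x
  out$values <- x$values[ids, , drop = FALSE]
  out$meta <- keep(x$meta)
  out$nutrients <- keep(x$nutrients)
  if (!is.null(out$meta)) rownames(out$meta) <- NULL
  if (!is.null(out$nutrients)) rownames(out$nutrients) <- NULL
  out
}

#' Restrict a spectra set to a wavelength window
#'
#' General band windowing; [trim_spectra()] is the fixed analysis-range
#' trim. Narrow windows are convenient for fast scans in examples and
#' simulation studies.
#'
#' @param x a `spectra_set`.
#' @param lower,upper window bounds in nm (inclusive).
#' @return a `spectra_set` on the restricted grid.
#' @export
window_spectra <- function(x, lower, upper) {
  w <- wavelengths(x)
  if (lower < min(w) || upper > max(w))
    stop("requested window ", lower, "-", upper,
         " nm exceeds grid ", min(w), "-", max(w), " nm")
  keep <- w >= lower & w <= upper
  out <- x
  out$wavelengths <- w[keep]
  out$values <- x$values[, keep, drop = FALSE]
  out
}

#' Trim spectra to the 350--1000 nm analysis range
#'
#' Removes the noisy marginal ranges below 350 nm and above 1000 nm
#' recorded by 325--1075 nm field spectrometers. The retained interval is
#' closed: 350 and 1000 nm are both kept, giving 651 bands. Values at
#' retained bands are unchanged, and trimming an already-trimmed set is a
#' no-op.
#'
#' @param x a `spectra_set` (kind `"reflectance"`).
#' @return a `spectra_set` on the 350--1000 nm grid.
#' @export
trim_spectra <- function(x) {
  w <- wavelengths(x)
  if (min(w) > 350L || max(w) < 1000L)
    stop("spectrum covers ", min(w), "-", max(w),
         " nm; cannot trim to 350-1000 nm (missing ",
         if (min(w) > 350L) paste0("350-", min(w) - 1L, " nm")
         else paste0(max(w) + 1L, "-1000 nm"), ")")
  window_spectra(x, 350L, 1000L)
}

# TRUE when the grid lies inside the trimmed analysis range
is_trimmed <- function(x) {
  w <- wavelengths(x)
  min(w) >= 350L && max(w) <= if (x$kind == "derivative") 999L else 1000L
}

#' First-derivative spectra
#'
#' Computes the first-order derivative spectrum from the difference in
#' reflectance between successive wavebands. The default convention is
#' the forward difference FD(lambda) = (R(lambda + 1) - R(lambda)) / 1 nm,
#' assigned to the lower wavelength, so the derivative grid drops the
#' last source band. A central-difference variant (interior bands only,
#' dropping both ends) is available via `method`.
#'
#' @param x a `spectra_set` of kind `"reflectance"`.
#' @param method `"forward"` (default) or `"central"`.
#' @return a `spectra_set` of kind `"derivative"`, units nm^-1.
#' @export
first_derivative <- function(x, method = c("forward", "central")) {
  method <- match.arg(method)
  if (x$kind != "reflectance")
    stop("first_derivative() expects reflectance input")
  b <- length(x$wavelengths)
  if (b < 2L) stop("need at least 2 bands to differentiate")
  if (method == "forward") {
    vals <- x$values[, -1L, drop = FALSE] - x$values[, -b, drop = FALSE]
    grid <- x$wavelengths[-b]
  } else {
    if (b < 3L) stop("need at least 3 bands for central differences")
    vals <- (x$values[, -(1:2), drop = FALSE] -
               x$values[, 1:(b - 2L), drop = FALSE]) / 2
    grid <- x$wavelengths[2:(b - 1L)]
  }
  spectra_set(vals, grid, sample_ids = sample_ids(x),
              meta = x$meta, nutrients = x$nutrients, kind = "derivative")
}
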