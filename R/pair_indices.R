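#' The ten two-band index families
#'
#' Enumerates the index families built from all band pairs: reflectance
#' at a single band (R), reflectance difference (D), ratio (RR),
#' normalized difference (ND) and inverse-reflectance difference (ID),
#' plus the same five forms applied to the first-derivative spectrum
#' (FD, FDD, FDRR, FDND, FDID).
#'
#' @return a data.frame with columns `name`, `arity` (1 or 2) and
#'   `source` (`"reflectance"` or `"derivative"`).
#' @export
index_families <- function() {
  data.frame(
    name   = c("R", "D", "RR", "ND", "ID",
               "FD", "FDD", "FDRR", "FDND", "FDID"),
    arity  = c(1L, 2L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L),
    source = rep(c("reflectance", "derivative"), each = 5L),
    stringsAsFactors = FALSE)
}

family_info <- function(family) {
  fams <- index_families()
  k <- match(family, fams$name)
  if (is.na(k))
    stop("unknown index family '", family, "'; see index_families()")
  fams[k, ]
}

# core pair formulas; zero denominators become NA (undefined marker),
# never Inf/NaN, so downstream correlation can drop them as missing
pair_values <- function(family, vi, vj) {
  switch(family,
    R    = vi,
    FD   = vi,
    D    = ,
    FDD  = vj - vi,
    RR   = ,
    FDRR = ifelse(vi == 0, NA_real_, vj / vi),
    ND   = ,
    FDND = ifelse(vj + vi == 0, NA_real_, (vj - vi) / (vj + vi)),
    ID   = ,
    FDID = ifelse(vi == 0 | vj == 0, NA_real_, 1 / vj - 1 / vi))
}

# pick the source values for a family; computes the forward-difference
# derivative on the fly when only reflectance is supplied
family_source_set <- function(family, s, fd = NULL) {
  info <- family_info(family)
  if (info$source == "reflectance") {
    if (s$kind != "reflectance") stop("family ", family,
                                      " needs reflectance input")
    s
  } else {
    if (!is.null(fd)) {
      if (fd$kind != "derivative")
        stop("fd must be a derivative spectra_set")
      fd
    } else if (s$kind == "derivative") s
    else first_derivative(s)
  }
}

band_col <- function(set, nm, what = "wavelength") {
  k <- match(as.integer(nm), set$wavelengths)
  if (is.na(k))
    stop(what, " ", nm, " nm is not on the ", set$kind, " grid (",
         min(set$wavelengths), "-", max(set$wavelengths), " nm)")
  k
}

#' Evaluate one two-band (or one-band) index at given wavelengths
#'
#' Computes the index value of `family` at bands `i` (and `j` for
#' two-band families) for every sample in the set. Zero denominators
#' yield `NA` (the undefined marker), never an error or infinity.
#'
#' @param family family name (see [index_families()]).
#' @param s a reflectance `spectra_set` (trimmed).
#' @param i,j wavelengths in nm; `j` ignored for one-band families.
#' @param fd optional matching derivative `spectra_set`; computed with
#'   the forward difference when omitted and needed.
#' @return named numeric vector, one value per sample.
#' @export
pair_index <- function(family, s, i, j = NULL, fd = NULL) {
  info <- family_info(family)
  src <- family_source_set(family, s, fd)
  vi <- src$values[, band_col(src, i), drop = TRUE]
  if (info$arity == 2L) {
    if (is.null(j)) stop("family ", family, " needs two wavelengths")
    vj <- src$values[, band_col(src, j), drop = TRUE]
  } else vj <- NULL
  out <- pair_values(info$name, vi, vj)
  names(out) <- sample_ids(src)
  out
}

#' All-pair index matrices for one family
#'
#' Evaluates a family over the complete combination of band pairs
#' (i, j) of the analysis grid, for every sample. For two-band families
#' the result is a 3-d array (i x j x sample); for the one-band families
#' R and FD it is a band x sample matrix. Undefined cells (zero
#' denominator) are `NA`.
#'
#' @param family family name (see [index_families()]).
#' @param s a reflectance `spectra_set`, trimmed to within 350--1000 nm.
#' @param fd optional matching derivative `spectra_set`.
#' @return numeric array (band_i x band_j x sample) or matrix
#'   (band x sample), dimnames the nm values and sample ids.
#' @export
pair_index_matrix <- function(family, s, fd = NULL) {
  if (s$kind == "reflectance" && !is_trimmed(s))
    stop("spectra extend outside 350-1000 nm; apply trim_spectra() first")
  info <- family_info(family)
  src <- family_source_set(family, s, fd)
  w <- src$wavelengths
  n <- n_samples(src)
  if (info$arity == 1L) {
    out <- t(src$values)
    dimnames(out) <- list(as.character(w), sample_ids(src))
    return(out)
  }
  b <- length(w)
  out <- array(NA_real_, dim = c(b, b, n),
               dimnames = list(as.character(w), as.character(w),
                               sample_ids(src)))
  for (k in seq_len(n)) {
    v <- src$values[k, ]
    vi <- matrix(v, b, b)          # value at i, constant across j
    vj <- t(vi)                    # value at j
    out[, , k] <- pair_values(info$name, vi, vj)
  }
  out
}
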