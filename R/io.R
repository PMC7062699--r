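#' Read spectra from disk
#'
#' Two dialects are supported, mirroring common field-spectrometer
#' exports:
#' \describe{
#'   \item{`wide_csv`}{one CSV with a `sample_id` column followed by one
#'     column per wavelength, headers the integer nm values.}
#'   \item{`asd_ascii`}{a per-sample text file with two whitespace-
#'     separated columns (wavelength nm, reflectance); lines starting
#'     with `#` are ignored.}
#' }
#' A metadata/nutrient sidecar CSV (columns `sample_id, species,
#' degradation, replicate, N, P, K`) can be attached via `sidecar`.
#'
#' @param path path to the CSV (wide_csv) or ASCII file (asd_ascii).
#' @param dialect `"wide_csv"` or `"asd_ascii"`.
#' @param sidecar optional path to the metadata/nutrient sidecar CSV.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, dialect = c("wide_csv", "asd_ascii"),
                         sidecar = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "wide_csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "sample_id")
      stop("wide_csv must have 'sample_id' as its first column")
    wl_chr <- names(df)[-1]
    wl <- suppressWarnings(as.integer(wl_chr))
    if (anyNA(wl))
      stop("non-integer wavelength column header(s): ",
           paste(wl_chr[is.na(wl)], collapse = ", "))
    vals <- as.matrix(df[, -1, drop = FALSE])
    ids <- as.character(df$sample_id)
  } else {
    df <- utils::read.table(path, comment.char = "#",
                            col.names = c("wavelength", "reflectance"))
    wl <- as.integer(round(df$wavelength))
    vals <- matrix(df$reflectance, nrow = 1)
    ids <- sub("\\.[^.]*$", "", basename(path))
  }
  side <- if (!is.null(sidecar)) read_sidecar(sidecar) else NULL
  spectra_set(vals, wl, sample_ids = ids,
              meta = side$meta, nutrients = side$nutrients)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("sample_id", "species", "degradation", "replicate",
            "N", "P", "K")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sidecar is missing column(s): ", paste(missing, collapse = ", "))
  list(meta = df[, c("sample_id", "species", "degradation", "replicate")],
       nutrients = df[, c("sample_id", "N", "P", "K")])
}

#' Write a spectra set to wide CSV (plus optional sidecar)
#'
#' Writes the dialects [read_spectra()] reads. Reflectance is written
#' with 15 significant digits so a write/read round trip reproduces
#' values to better than 1e-9.
#'
#' @param x a `spectra_set`.
#' @param path output CSV path.
#' @param sidecar optional path for the metadata/nutrient sidecar CSV
#'   (requires both `meta` and `nutrients` to be present).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, sidecar = NULL) {
  df <- data.frame(sample_id = sample_ids(x), check.names = FALSE)
  vals <- x$values
  for (k in seq_along(x$wavelengths))
    df[[as.character(x$wavelengths[k])]] <- format(vals[, k], digits = 15,
                                                   scientific = TRUE,
                                                   trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    if (is.null(x$meta) || is.null(x$nutrients))
      stop("cannot write sidecar: meta and nutrients must both be attached")
    side <- cbind(x$meta,
                  x$nutrients[match(x$meta$sample_id,
                                    x$nutrients$sample_id),
                              c("N", "P", "K")])
    utils::write.csv(side, sidecar, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
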