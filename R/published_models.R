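#' Registry of published field-calibrated nutrient models
#'
#' Loads the fixed prediction equations calibrated on a temperate
#' degraded-vegetation field survey, shipped as a versioned JSON
#' resource: twelve stepwise models (families D, ND, FD, FDD crossed
#' with leaf N, P, K) and nine single-index linear equations (empirical
#' indices RES, DVI and FD730-570 per nutrient). Coefficients are
#' stored digit-for-digit as printed in their source equations.
#'
#' The stepwise entries name each predictor by family and one band
#' (e.g. `D_937`, the reflectance-difference value involving 937 nm);
#' the partner band of the two-band families was not recorded with the
#' equations, so these predictors are abstract named inputs the caller
#' must supply to [predict.nutrient_model()]. Models fitted by this
#' package's own [stepwise_fit()] always record both bands.
#'
#' @return a named list of `nutrient_model` objects keyed by id (e.g.
#'   `"D_N"`, `"ND_K"`, `"RES_K"`), with attributes `version` and
#'   `provenance`.
#' @export
published_models <- function() {
  path <- system.file("extdata", "published_models.json",
                      package = "nutrispec", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (m in obj$stepwise) {
    terms <- data.frame(
      label = vapply(m$terms, `[[`, "", "label"),
      family = m$family,
      bands = vapply(m$terms, function(tm) as.character(tm$band), ""),
      coefficient = vapply(m$terms, `[[`, 0, "coefficient"),
      p = NA_real_, stringsAsFactors = FALSE)
    out[[m$id]] <- new_nutrient_model(
      m$nutrient, m$intercept, terms, fit_r2 = m$fit_r2,
      adj_r2 = m$adj_r2, id = m$id, provenance = obj$provenance)
  }
  for (m in obj$single_index) {
    terms <- data.frame(label = m$index, family = "empirical",
                        bands = NA_character_, coefficient = m$slope,
                        p = NA_real_, stringsAsFactors = FALSE)
    out[[m$id]] <- new_nutrient_model(
      m$nutrient, m$intercept, terms, fit_r2 = m$r2, id = m$id,
      provenance = obj$provenance)
  }
  attr(out, "version") <- obj$version
  attr(out, "provenance") <- obj$provenance
  out
}

#' Fetch one published model by id
#'
#' @param id model id, e.g. `"D_N"`, `"FD_K"`, `"RES_K"`; see
#'   [published_models()].
#' @return a `nutrient_model`.
#' @export
published_model <- function(id) {
  reg <- published_models()
  if (!id %in% names(reg))
    stop("unknown model id '", id, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[id]]
}
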