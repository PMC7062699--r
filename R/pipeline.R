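#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. With `input = NULL` the pipeline simulates its own dataset
#' via [generate_dataset()]; otherwise spectra are read from disk.
#'
#' @param input path to a spectra file, or `NULL` to simulate.
#' @param dialect input dialect for [read_spectra()].
#' @param sidecar optional metadata/nutrient sidecar CSV path.
#' @param out_dir directory for run artifacts (created if absent).
#' @param seed master seed for simulation and the split draw.
#' @param alpha per-cell significance level of the scan (in (0, 1)).
#' @param k sensitive bands per nutrient (>= 1, default 22).
#' @param entry_p,removal_p stepwise thresholds (in (0, 1)).
#' @param fd_method derivative convention, `"forward"` or `"central"`.
#' @param scan_families families scanned for sensitive bands (default
#'   all ten).
#' @param fit_families two-band/one-band families given to the stepwise
#'   stage (default D, ND, FD, FDD).
#' @param scan_window `c(lower, upper)` nm window for the scan stage;
#'   the full 350--1000 nm analysis range by default, narrower windows
#'   make exploratory runs fast.
#' @param quiet suppress stage messages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, dialect = "wide_csv",
                            sidecar = NULL, out_dir = tempfile("nutrispec_"),
                            seed = 1L, alpha = 0.05, k = 22L,
                            entry_p = 0.05, removal_p = 0.10,
                            fd_method = "forward",
                            scan_families = index_families()$name,
                            fit_families = c("D", "ND", "FD", "FDD"),
                            scan_window = c(350L, 1000L),
                            quiet = FALSE) {
  for (thr in c(alpha = alpha, entry_p = entry_p, removal_p = removal_p))
    if (thr <= 0 || thr >= 1) stop("thresholds must lie in (0, 1)")
  if (k < 1L) stop("k must be >= 1")
  bad <- setdiff(scan_families, index_families()$name)
  if (length(bad)) stop("unknown scan famil(ies): ",
                        paste(bad, collapse = ", "))
  structure(list(input = input, dialect = dialect, sidecar = sidecar,
                 out_dir = out_dir, seed = as.integer(seed),
                 alpha = alpha, k = as.integer(k), entry_p = entry_p,
                 removal_p = removal_p, fd_method = fd_method,
                 scan_families = scan_families,
                 fit_families = fit_families,
                 scan_window = as.integer(scan_window), quiet = quiet),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the YAML file;
#' omitted fields take their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_msg <- function(quiet, ...) if (!quiet) message("[nutrispec] ", ...)

#' Run the full estimation pipeline
#'
#' Sequences every stage: simulate (or read) spectra, trim the marginal
#' bands, differentiate, scan all configured index families against
#' leaf N, P and K on the calibration partition, tally significant
#' correlations, select sensitive bands, fit stepwise models per
#' family, evaluate the empirical-index registry, and validate the best
#' model per nutrient on the held-out index-validation samples. All
#' artifacts (band counts, sensitive bands, model JSONs, validation
#' CSV, registry YAML and a manifest recording config, seed and package
#' version) are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the dataset, splits, counts, selected
#'   bands, fitted models, empirical-index table and validation
#'   reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- config$quiet

  if (is.null(config$input)) {
    stage_msg(q, "simulating dataset (seed ", config$seed, ")")
    data <- generate_dataset(design_spec(seed = config$seed))
  } else {
    stage_msg(q, "reading spectra from ", config$input)
    data <- read_spectra(config$input, config$dialect, config$sidecar)
  }
  if (is.null(data$nutrients))
    stop("stage scan: dataset carries no nutrient table")

  data <- trim_spectra(data)
  splits <- split_calibration_validation(data, seed = config$seed)
  cal <- splits$calibration
  stage_msg(q, n_samples(data), " samples trimmed; ",
            n_samples(cal), " calibration / ",
            n_samples(splits$validation), " validation (",
            n_samples(splits$index_validation), " for new indices)")

  scan_set <- window_spectra(cal, config$scan_window[1],
                             config$scan_window[2])
  fd_scan <- first_derivative(scan_set, method = config$fd_method)

  nutrients <- c("N", "P", "K")
  selections <- list(); counts_all <- list()
  for (nut in nutrients) {
    stage_msg(q, "scanning ", length(config$scan_families),
              " families vs leaf ", nut)
    maps <- lapply(config$scan_families, function(fam)
      correlation_scan(scan_set, fam, nut, fd = fd_scan))
    counts <- count_significant(maps, alpha = config$alpha, quiet = TRUE)
    counts_all[[nut]] <- counts
    selections[[nut]] <- select_sensitive_bands(counts, k = config$k)
    write_band_counts(counts,
                      file.path(config$out_dir,
                                paste0("band_counts_", nut, ".csv")))
    write_band_counts(selections[[nut]],
                      file.path(config$out_dir,
                                paste0("sensitive_bands_", nut, ".csv")))
  }

  fd_cal <- first_derivative(scan_set, method = config$fd_method)
  models <- list()
  for (nut in nutrients) {
    bands <- selections[[nut]]$band
    if (length(bands) < 2L) {
      stage_msg(q, "too few sensitive bands for leaf ", nut,
                "; skipping model fits")
      next
    }
    for (fam in config$fit_families) {
      pt <- predictor_table(scan_set, fam, bands, fd = fd_cal)
      m <- stepwise_fit(pt$X, cal$nutrients[[nut]],
                        entry_p = config$entry_p,
                        removal_p = config$removal_p,
                        nutrient = nut, term_info = pt$info)
      m$id <- paste0(fam, "_", nut, "_fitted")
      models[[m$id]] <- m
      write_model(m, file.path(config$out_dir,
                               paste0("model_", m$id, ".json")))
    }
  }

  stage_msg(q, "evaluating empirical-index registry")
  registry <- empirical_index_registry()
  emp <- empirical_indices(data, registry = registry)
  utils::write.csv(emp, file.path(config$out_dir,
                                  "empirical_indices.csv"),
                   row.names = FALSE)
  write_index_registry(registry,
                       file.path(config$out_dir, "index_registry.yaml"))

  stage_msg(q, "validating fitted models on held-out samples")
  val_set <- window_spectra(splits$index_validation,
                            config$scan_window[1], config$scan_window[2])
  fd_val <- first_derivative(val_set, method = config$fd_method)
  reports <- list()
  for (nut in nutrients) {
    cand <- Filter(function(m) identical(m$nutrient, nut) && !m$empty,
                   models)
    if (!length(cand)) next
    best <- cand[[which.max(vapply(cand, `[[`, 0, "adj_r2"))]]
    newdata <- lapply(seq_len(nrow(best$terms)), function(i) {
      bands <- as.integer(strsplit(best$terms$bands[i], "/")[[1]])
      pair_index(best$terms$family[i], val_set, i = bands[1],
                 j = if (length(bands) > 1) bands[2], fd = fd_val)
    })
    names(newdata) <- best$terms$label
    pred <- predict(best, newdata)
    rep0 <- validate_predictions(pred,
                                 splits$index_validation$nutrients[[nut]])
    reports[[nut]] <- c(nutrient = nut, model = best$id,
                        rep0[c("slope", "intercept", "r2", "p", "n")])
  }
  if (length(reports)) {
    vdf <- do.call(rbind, lapply(reports, as.data.frame))
    utils::write.csv(vdf, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "nutrispec",
    version = as.character(utils::packageVersion("nutrispec")),
    config = unclass(config),
    n_samples = n_samples(data),
    n_calibration = n_samples(cal),
    n_validation = n_samples(splits$validation),
    n_index_validation = n_samples(splits$index_validation),
    n_families = nrow(index_families()),
    n_empirical_indices = length(registry))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  stage_msg(q, "run complete: ", config$out_dir)
  invisible(list(data = data, splits = splits, counts = counts_all,
                 sensitive_bands = selections, models = models,
                 empirical = emp, validation = reports,
                 manifest = manifest))
}
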