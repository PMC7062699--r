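# run expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic study design
#'
#' The sampling design the generator emulates: a fully crossed
#' species x degradation-intensity x replicate layout. The default
#' (6 species, 3 intensities, 8 replicate plants) gives 144 samples.
#'
#' @param n_species number of species labels (default 6).
#' @param n_intensities number of degradation levels, at most 3
#'   (light, moderate, severe; default 3).
#' @param n_replicates replicate plants per species x intensity cell
#'   (default 8).
#' @param seed integer master seed; split internally into independent
#'   substreams for species curves, nutrient draws and spectral noise,
#'   so reseeding one purpose cannot perturb the others.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_species = 6L, n_intensities = 3L,
                        n_replicates = 8L, seed = 1L) {
  stopifnot(n_species >= 1L, n_intensities >= 1L, n_intensities <= 3L,
            n_replicates >= 1L)
  structure(list(n_species = as.integer(n_species),
                 n_intensities = as.integer(n_intensities),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Nutrient-to-spectrum effect structure
#'
#' Controls how simulated leaf nutrients imprint on the simulated
#' spectra. Each nutrient has a baseline mean and sd (mg g-1) and a set
#' of Gaussian absorption features (center nm, width nm, weight in
#' reflectance units per nutrient standard deviation) whose depth
#' scales with the sample's standardized nutrient value. Degradation
#' intensity shifts nutrient means (in sd units, monotone decreasing
#' from light to severe by default) and adds a small flat albedo offset
#' (degraded canopies reflect more in the visible). Smooth species-
#' level random curves and i.i.d. spectral noise complete the model.
#'
#' Baseline means (N 20, P 150, K 60 mg g-1) are placeholders chosen to
#' sit in the range implied by published field-calibrated equation
#' intercepts; no distributional summaries of real field measurements
#' stand behind them.
#'
#' @param nutrients named list per nutrient of `list(mean, sd)`.
#' @param features named list per nutrient of data.frames with columns
#'   `center` (nm, within 350--1000), `width` (nm, > 0) and `weight`
#'   (reflectance depth per sd of nutrient).
#' @param intensity_offsets nutrient-mean shifts in sd units for light,
#'   moderate, severe.
#' @param intensity_albedo flat reflectance offsets per intensity.
#' @param noise_sd i.i.d. spectral noise sd (reflectance units, >= 0).
#' @param species_sd amplitude of the smooth species-level curves.
#' @param nutrient_cv_floor lower clamp on drawn nutrient values as a
#'   fraction of the mean (keeps them strictly positive).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(
    nutrients = list(N = list(mean = 20, sd = 5),
                     P = list(mean = 150, sd = 30),
                     K = list(mean = 60, sd = 15)),
    features = list(
      N = data.frame(center = c(560, 705, 930),
                     width = c(20, 15, 18),
                     weight = c(0.006, 0.010, 0.004)),
      P = data.frame(center = c(420, 830),
                     width = c(15, 20),
                     weight = c(0.008, 0.006)),
      K = data.frame(center = c(460, 919),
                     width = c(15, 15),
                     weight = c(0.008, 0.006))),
    intensity_offsets = c(light = 0.5, moderate = 0, severe = -0.5),
    intensity_albedo = c(light = 0, moderate = 0.01, severe = 0.02),
    noise_sd = 0.002, species_sd = 0.01, nutrient_cv_floor = 0.1) {
  stopifnot(noise_sd >= 0, species_sd >= 0)
  for (nut in names(features)) {
    ft <- features[[nut]]
    if (is.null(ft) || !nrow(ft)) next
    if (any(ft$width <= 0)) stop("feature widths must be > 0")
    if (any(ft$center < 350 | ft$center > 1000))
      stop("feature at ", ft$center[ft$center < 350 | ft$center > 1000][1],
           " nm lies outside the 350-1000 nm analysis grid")
  }
  structure(list(nutrients = nutrients, features = features,
                 intensity_offsets = intensity_offsets,
                 intensity_albedo = intensity_albedo,
                 noise_sd = noise_sd, species_sd = species_sd,
                 nutrient_cv_floor = nutrient_cv_floor),
            class = "effect_spec")
}

# smooth green-leaf reflectance template on an nm grid: low visible
# floor, green peak near 552 nm, chlorophyll well near 680 nm, steep
# red edge, NIR plateau ~0.45
leaf_template <- function(w) {
  logistic <- function(z) 1 / (1 + exp(-z))
  0.05 +
    0.38 * logistic((w - 718) / 12) +
    0.06 * exp(-(w - 552)^2 / (2 * 35^2)) -
    0.02 * exp(-(w - 680)^2 / (2 * 15^2)) +
    0.01 * logistic((w - 420) / 40)
}

#' Generate a synthetic leaf-spectra dataset
#'
#' Builds a full synthetic dataset on the native 325--1075 nm
#' spectrometer grid (so the marginal-band trim is exercised): a smooth
#' green-leaf template, plus per-nutrient Gaussian absorption features
#' whose depth tracks each sample's standardized nutrient value, plus
#' smooth species-level random curves, intensity albedo offsets, and
#' i.i.d. noise. Nutrients are drawn from normal distributions whose
#' means shift monotonically with degradation intensity. Deterministic
#' for a fixed `design$seed`.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @return a `spectra_set` with metadata and nutrient table attached.
#' @export
generate_dataset <- function(design = design_spec(),
                             effects = effect_spec()) {
  stopifnot(inherits(design, "design_spec"),
            inherits(effects, "effect_spec"))
  levels <- c("light", "moderate", "severe")[seq_len(design$n_intensities)]
  species <- paste0("sp", seq_len(design$n_species))
  grid <- 325:1075
  layout <- expand.grid(replicate = seq_len(design$n_replicates),
                        species = species, degradation = levels,
                        stringsAsFactors = FALSE)
  n <- nrow(layout)
  layout$sample_id <- sprintf("%s_%s_r%d", layout$species,
                              layout$degradation, layout$replicate)
  with_seed(design$seed, {
    sub <- sample.int(2^31 - 2, 3)
    # species-level smooth curves: low-order cosine series
    set.seed(sub[1])
    sp_curves <- sapply(species, function(s) {
      a <- stats::rnorm(3, 0, effects$species_sd / (1:3))
      ph <- stats::runif(3, 0, 2 * pi)
      rowSums(sapply(1:3, function(h)
        a[h] * cos(2 * pi * h * (grid - 350) / 1400 + ph[h])))
    })
    # nutrient draws per sample
    set.seed(sub[2])
    nut <- sapply(names(effects$nutrients), function(nm) {
      par <- effects$nutrients[[nm]]
      shift <- effects$intensity_offsets[layout$degradation] * par$sd
      pmax(effects$nutrient_cv_floor * par$mean,
           par$mean + shift + stats::rnorm(n, 0, par$sd))
    })
    # spectra
    set.seed(sub[3])
    base <- leaf_template(grid)
    vals <- matrix(rep(base, each = n), n, length(grid))
    for (nm in names(effects$features)) {
      ft <- effects$features[[nm]]
      if (is.null(ft) || !nrow(ft)) next
      par <- effects$nutrients[[nm]]
      z <- (nut[, nm] - par$mean) / par$sd
      for (f in seq_len(nrow(ft))) {
        shape <- exp(-(grid - ft$center[f])^2 / (2 * ft$width[f]^2))
        vals <- vals - ft$weight[f] * outer(z, shape)
      }
    }
    vals <- vals + t(sp_curves[, layout$species]) +
      effects$intensity_albedo[layout$degradation]
    if (effects$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0,
                                         effects$noise_sd),
                            nrow(vals), ncol(vals))
    nutrients <- data.frame(sample_id = layout$sample_id,
                            N = nut[, "N"], P = nut[, "P"],
                            K = nut[, "K"], stringsAsFactors = FALSE)
    meta <- layout[, c("sample_id", "species", "degradation",
                       "replicate")]
    spectra_set(vals, grid, sample_ids = layout$sample_id, meta = meta,
                nutrients = nutrients)
  })
}

# largest-remainder integer allocation of `total` over stratum sizes
allocate_stratified <- function(sizes, total) {
  quota <- sizes * total / sum(sizes)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  pmin(base, sizes)
}

#' Split a dataset into calibration and validation partitions
#'
#' Reproduces the field study's partitioning: from 144 samples, 64 go
#' to calibration (model fitting), the remaining 80 to validation, and
#' a 30-sample subset of the validation partition is reserved for
#' validating the newly fitted indices. Other dataset sizes use the
#' same proportions (44 percent calibration; subset 37.5 percent of
#' validation). Splits are stratified by degradation intensity as
#' evenly as integer counts allow and are deterministic per seed.
#'
#' @param x a `spectra_set` (>= 3 samples).
#' @param seed integer seed for the split draw.
#' @return list with `spectra_set` elements `calibration`,
#'   `validation` and `index_validation` (subset of `validation`).
#' @export
split_calibration_validation <- function(x, seed = 1L) {
  n <- n_samples(x)
  if (n < 3L) stop("dataset has fewer than 3 samples")
  n_cal <- if (n == 144L) 64L else max(1L, round(n * 64 / 144))
  strata <- if (!is.null(x$meta)) as.character(x$meta$degradation)
            else rep("all", n)
  ids <- sample_ids(x)
  with_seed(seed, {
    groups <- split(ids, strata)
    alloc <- allocate_stratified(lengths(groups), n_cal)
    cal_ids <- unlist(mapply(function(g, k) sample(g, k), groups, alloc,
                             SIMPLIFY = FALSE), use.names = FALSE)
    val_ids <- setdiff(ids, cal_ids)
    n_sub <- if (n == 144L) 30L else
      max(1L, round(0.375 * length(val_ids)))
    vgroups <- split(val_ids, strata[match(val_ids, ids)])
    valloc <- allocate_stratified(lengths(vgroups), n_sub)
    sub_ids <- unlist(mapply(function(g, k) sample(g, k), vgroups,
                             valloc, SIMPLIFY = FALSE), use.names = FALSE)
    list(calibration = subset_samples(x, ids[ids %in% cal_ids]),
         validation = subset_samples(x, ids[ids %in% val_ids]),
         index_validation = subset_samples(x, ids[ids %in% sub_ids]))
  })
}
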