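# toy spectra on a small contiguous grid, values deterministic
toy_set <- function(n = 3, lower = 350, upper = 354, seed = 42,
                    nutrients = NULL, meta = NULL) {
  grid <- lower:upper
  set.seed(seed)
  vals <- matrix(runif(n * length(grid), 0.05, 0.6), n, length(grid))
  spectra_set(vals, grid, sample_ids = paste0("S", seq_len(n)),
              meta = meta, nutrients = nutrients)
}

# full-range (325-1075) flat or ramped single-sample spectrum
full_range_set <- function(value = 0.3, slope = 0, n = 1) {
  grid <- 325:1075
  row <- value + slope * grid
  vals <- matrix(rep(row, each = n), n, length(grid))
  suppressWarnings(spectra_set(vals, grid,
                               sample_ids = paste0("S", seq_len(n))))
}

# minimal correlation_map built by hand for tally tests
manual_map <- function(bands, r, p, nutrient = "N", n_eff = 10L) {
  if (is.matrix(r)) {
    dimnames(r) <- dimnames(p) <- list(bands, bands)
    ne <- matrix(n_eff, length(bands), length(bands))
  } else {
    names(r) <- names(p) <- bands
    ne <- setNames(rep(n_eff, length(bands)), bands)
  }
  structure(list(family = if (is.matrix(r)) "D" else "R",
                 nutrient = nutrient, bands = as.integer(bands),
                 r = r, p = p, n_eff = ne, min_n = 3L,
                 n_samples = n_eff),
            class = "correlation_map")
}

# a truly null effect structure: no nutrient-linked features AND no
# shared degradation factor (the default generator shifts both
# nutrients and spectra with intensity, which links them)
null_effects <- function(noise_sd = 0.002) {
  effect_spec(features = list(),
              intensity_offsets = c(light = 0, moderate = 0, severe = 0),
              intensity_albedo = c(light = 0, moderate = 0, severe = 0),
              noise_sd = noise_sd)
}

# narrow planted absorption lines (3 nm sd) so band-level recovery at
# +/- 2 nm is well defined; weights are 4x the noise sd
planted_effects <- function(planted, weight = 0.008, width = 3,
                            noise_sd = 0.002) {
  effect_spec(
    features = lapply(planted, function(ctr)
      data.frame(center = ctr, width = width, weight = weight)),
    intensity_offsets = c(light = 0, moderate = 0, severe = 0),
    intensity_albedo = c(light = 0, moderate = 0, severe = 0),
    noise_sd = noise_sd)
}

# independent greedy stepwise oracle: explicit RSS-based partial-F
# p-values, no reuse of the package's fitting path
oracle_stepwise <- function(X, y, entry_p = 0.05, removal_p = 0.10) {
  X <- as.matrix(X)
  rss <- function(cols) {
    A <- cbind(1, X[, cols, drop = FALSE])
    fit <- qr(A)
    if (fit$rank < ncol(A)) return(NA_real_)
    sum(qr.resid(fit, y)^2)
  }
  partial_f_p <- function(small, big) {
    r0 <- rss(small); r1 <- rss(big)
    if (is.na(r1)) return(NA_real_)
    df2 <- length(y) - length(big) - 1
    f <- (r0 - r1) / (r1 / df2)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  inc <- character(0)
  repeat {
    pool <- setdiff(colnames(X), inc)
    if (!length(pool)) break
    ps <- vapply(pool, function(c0) partial_f_p(inc, c(inc, c0)),
                 numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) > entry_p) break
    inc <- c(inc, pool[which.min(ps)])
    repeat {
      ps_in <- vapply(inc, function(c0)
        partial_f_p(setdiff(inc, c0), inc), numeric(1))
      if (max(ps_in, na.rm = TRUE) <= removal_p) break
      inc <- inc[-which.max(ps_in)]
    }
  }
  inc
}
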