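#' Pearson correlation with significance
#'
#' Pearson's r with a two-sided p-value from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)). Pairs in which either value is
#' missing (the undefined marker of the index engine) are dropped first;
#' the effective sample size after dropping is returned. Cells with
#' fewer than 3 effective pairs or zero variance are reported invalid
#' (`r` and `p` are `NA`) rather than silently zeroed.
#'
#' @param x,y aligned numeric vectors (same length, same sample order).
#' @return list with elements `r`, `p`, `n_effective`, `valid`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n_effective = n,
                valid = FALSE))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n_effective = n, valid = TRUE)
}

# column-wise NA-aware Pearson r/p of each column of X against y;
# vectorized version of pearson_with_p used by the all-pair scan
col_pearson <- function(X, y, min_n) {
  M <- !is.na(X)
  Xz <- X
  Xz[!M] <- 0
  n <- colSums(M)
  sx <- colSums(Xz)
  sxx <- colSums(Xz * Xz)
  sy <- as.numeric(crossprod(M, y))
  syy <- as.numeric(crossprod(M, y * y))
  sxy <- as.numeric(crossprod(Xz, y))
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  bad <- n < min_n | vx <= 0 | vy <= 0
  r <- rep(NA_real_, ncol(X))
  r[!bad] <- pmin(1, pmax(-1, (n * sxy - sx * sy)[!bad] /
                            sqrt(vx[!bad] * vy[!bad])))
  p <- rep(NA_real_, ncol(X))
  ok1 <- !bad & abs(r) == 1
  p[ok1] <- 0
  ok <- !bad & abs(r) < 1
  tval <- r[ok] * sqrt((n[ok] - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tval), df = n[ok] - 2)
  list(r = r, p = p, n_eff = as.integer(n))
}

#' Correlate one index family with a nutrient over all band pairs
#'
#' Builds the index values of `family` for every ordered band pair
#' (i, j) (or every single band for the one-band families) and
#' correlates each cell with the chosen leaf nutrient across samples.
#' Cells with too few defined values (`min_n`) or zero variance are
#' marked invalid (`NA`), never zeroed.
#'
#' @param x a `spectra_set` with an attached nutrient table, trimmed to
#'   within 350--1000 nm.
#' @param family family name (see [index_families()]).
#' @param nutrient `"N"`, `"P"` or `"K"`.
#' @param fd optional matching derivative `spectra_set`.
#' @param min_n minimum effective sample size for a valid cell; default
#'   `max(3, ceiling(n/2))` so marker-heavy derivative-ratio families
#'   cannot dominate by chance.
#' @return an object of class `correlation_map`: for two-band families
#'   `r`, `p` and `n_eff` are band x band matrices; for R and FD they
#'   are per-band vectors.
#' @export
correlation_scan <- function(x, family, nutrient = c("N", "P", "K"),
                             fd = NULL, min_n = NULL) {
  nutrient <- match.arg(nutrient)
  if (is.null(x$nutrients))
    stop("spectra set has no nutrient table; nutrient '", nutrient,
         "' unavailable")
  if (n_samples(x) < 3L) stop("need at least 3 samples")
  if (x$kind == "reflectance" && !is_trimmed(x))
    stop("spectra extend outside 350-1000 nm; apply trim_spectra() first")
  y <- x$nutrients[[nutrient]]
  if (is.null(min_n)) min_n <- max(3L, ceiling(n_samples(x) / 2))
  info <- family_info(family)
  src <- family_source_set(family, x, fd)
  w <- src$wavelengths
  b <- length(w)
  if (info$arity == 1L) {
    res <- col_pearson(src$values, y, min_n)
    out <- list(family = family, nutrient = nutrient, bands = w,
                r = stats::setNames(res$r, w),
                p = stats::setNames(res$p, w),
                n_eff = stats::setNames(res$n_eff, w),
                min_n = min_n, n_samples = n_samples(x))
  } else {
    r <- p <- matrix(NA_real_, b, b, dimnames = list(w, w))
    n_eff <- matrix(NA_integer_, b, b, dimnames = list(w, w))
    vals <- src$values
    for (k in seq_len(b)) {
      vi <- vals[, k]
      X <- pair_values(info$name, matrix(vi, nrow(vals), b), vals)
      res <- col_pearson(X, y, min_n)
      r[k, ] <- res$r
      p[k, ] <- res$p
      n_eff[k, ] <- res$n_eff
    }
    out <- list(family = family, nutrient = nutrient, bands = w,
                r = r, p = p, n_eff = n_eff,
                min_n = min_n, n_samples = n_samples(x))
  }
  structure(out, class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  arity <- if (is.matrix(x$r)) "band pairs" else "single bands"
  n_sig <- sum(x$p < 0.05, na.rm = TRUE)
  cat("<correlation_map> family ", x$family, " vs leaf ", x$nutrient,
      ", ", length(x$bands), " bands (", arity, "), ",
      n_sig, " cells with p < 0.05\n", sep = "")
  invisible(x)
}

#' Count significant correlations per band
#'
#' Tallies, for every wavelength, how many significant index--nutrient
#' correlation cells that wavelength participates in across a list of
#' family maps: a significant two-band cell (i, j) increments both i
#' and j, a significant one-band cell increments its band. The band
#' with the largest tally across families is the most nutrient-
#' sensitive.
#'
#' The default follows the raw per-cell threshold convention (`p <
#' alpha`, no multiple-testing correction) of correlation-map band
#' screening; the expected false-positive cell count under the null is
#' reported via `message()` as a safety rail, and `adjust = "BH"`
#' switches to Benjamini-Hochberg adjusted p-values across all cells of
#' all supplied maps.
#'
#' @param maps list of [correlation_scan()] results sharing one
#'   nutrient.
#' @param alpha per-cell significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param quiet suppress the expected-false-positive message.
#' @return an object of class `band_counts`: data.frame with `band`,
#'   `count` and `best_abs_r` (largest |r| among that band's
#'   significant cells), plus `nutrient` and `alpha` attributes.
#' @export
count_significant <- function(maps, alpha = 0.05,
                              adjust = c("none", "BH"), quiet = FALSE) {
  adjust <- match.arg(adjust)
  if (!length(maps)) stop("empty map list")
  if (inherits(maps, "correlation_map")) maps <- list(maps)
  nutrients <- unique(vapply(maps, `[[`, "", "nutrient"))
  if (length(nutrients) != 1L)
    stop("maps mix nutrients: ", paste(nutrients, collapse = ", "))
  all_bands <- sort(unique(unlist(lapply(maps, `[[`, "bands"))))
  counts <- stats::setNames(integer(length(all_bands)), all_bands)
  best_r <- stats::setNames(rep(NA_real_, length(all_bands)), all_bands)
  p_all <- unlist(lapply(maps, function(m) as.numeric(m$p)))
  n_cells <- sum(!is.na(p_all))
  if (adjust == "BH") {
    adj <- stats::p.adjust(p_all, method = "BH")
    offsets <- cumsum(c(0, vapply(maps, function(m) length(m$p), 0)))
  }
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    p <- if (adjust == "BH")
      array(adj[(offsets[k] + 1):offsets[k + 1]], dim = dim(m$p) %||%
              length(m$p)) else m$p
    sig <- !is.na(p) & p < alpha
    if (!any(sig)) next
    bchar <- as.character(m$bands)
    if (is.matrix(m$r)) {
      idx <- which(sig, arr.ind = TRUE)
      hits <- c(bchar[idx[, 1]], bchar[idx[, 2]])
      tab <- table(hits)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      rs <- abs(m$r[sig])
      for (d in 1:2) {
        agg <- tapply(rs, bchar[idx[, d]], max)
        best_r[names(agg)] <- pmax(best_r[names(agg)], agg, na.rm = TRUE)
      }
    } else {
      tab <- table(bchar[sig])
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      agg <- tapply(abs(m$r[sig]), bchar[sig], max)
      best_r[names(agg)] <- pmax(best_r[names(agg)], agg, na.rm = TRUE)
    }
  }
  if (!quiet && adjust == "none")
    message("expected false-positive cells under the null at alpha = ",
            alpha, ": ", round(alpha * n_cells, 1), " of ", n_cells)
  structure(
    data.frame(band = all_bands, count = as.integer(counts),
               best_abs_r = as.numeric(best_r), row.names = NULL),
    nutrient = nutrients, alpha = alpha, class = c("band_counts",
                                                   "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the most nutrient-sensitive bands
#'
#' Ranks bands by their significant-correlation tally and returns the
#' top `k`. Ties are broken deterministically: larger count first, then
#' larger best |r| among the band's significant cells, then lower
#' wavelength. Bands with zero count are never selected; if fewer than
#' `k` bands have a positive count, all of them are returned with a
#' warning.
#'
#' @param counts a [count_significant()] result.
#' @param k number of bands to select (default 22 per nutrient).
#' @return an object of class `sensitive_bands`: data.frame with
#'   `rank`, `band`, `count`, `best_abs_r`; `nutrient` attribute
#'   carried over.
#' @export
select_sensitive_bands <- function(counts, k = 22L) {
  if (k < 1L) stop("k must be >= 1")
  pos <- counts[counts$count > 0L, , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no band has a significant correlation; empty selection")
  } else if (nrow(pos) < k) {
    warning("only ", nrow(pos), " band(s) with positive count; ",
            "returning all of them (k = ", k, ")")
  }
  ord <- order(-pos$count, -pos$best_abs_r, pos$band)
  sel <- utils::head(pos[ord, , drop = FALSE], k)
  out <- data.frame(rank = seq_len(nrow(sel)), band = sel$band,
                    count = sel$count, best_abs_r = sel$best_abs_r,
                    row.names = NULL)
  structure(out, nutrient = attr(counts, "nutrient"), k = k,
            class = c("sensitive_bands", "data.frame"))
}

#' Pairwise degradation-intensity separability at one band
#'
#' Welch two-sample t-tests of reflectance at a single wavelength
#' between each pair of degradation-intensity groups (light, moderate,
#' severe). Degenerate groups (zero variance in both) fall back to an
#' exact mean comparison: p = 1 when the means are equal, 0 otherwise.
#'
#' @param x a `spectra_set` with attached metadata.
#' @param band wavelength in nm.
#' @return data.frame with columns `group1`, `group2`, `t`, `p`.
#' @export
degradation_ttest <- function(x, band) {
  if (is.null(x$meta)) stop("spectra set has no sample metadata")
  v <- x$values[, band_col(x, band), drop = TRUE]
  g <- as.character(x$meta$degradation)
  levels <- c("light", "moderate", "severe")
  missing <- setdiff(levels, unique(g))
  if (length(missing))
    stop("missing degradation group(s): ", paste(missing, collapse = ", "))
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  pairs <- utils::combn(levels, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- v[g == pr[1]]; b <- v[g == pr[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      c(t = 0, p = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b)
      c(t = unname(tt$statistic), p = tt$p.value)
    }
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             t = res["t", ], p = res["p", ], row.names = NULL)
}

#' Export the significant cells of a correlation map as CSV
#'
#' Writes one row per significant valid cell: family, i, j (empty for
#' one-band families), r, p, effective n. A companion to array exports
#' for downstream contour plotting.
#'
#' @param map a [correlation_scan()] result.
#' @param path output CSV path.
#' @param alpha significance threshold for inclusion.
#' @return `path`, invisibly.
#' @export
write_correlation_map <- function(map, path, alpha = 0.05) {
  sig <- !is.na(map$p) & map$p < alpha
  if (is.matrix(map$r)) {
    idx <- which(sig, arr.ind = TRUE)
    df <- data.frame(family = map$family, nutrient = map$nutrient,
                     i = map$bands[idx[, 1]], j = map$bands[idx[, 2]],
                     r = map$r[sig], p = map$p[sig],
                     n_effective = map$n_eff[sig])
  } else {
    df <- data.frame(family = map$family, nutrient = map$nutrient,
                     i = map$bands[sig], j = NA_integer_,
                     r = map$r[sig], p = map$p[sig],
                     n_effective = map$n_eff[sig])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export band significance counts as CSV
#'
#' @param counts a [count_significant()] or [select_sensitive_bands()]
#'   result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_counts <- function(counts, path) {
  df <- as.data.frame(counts)
  df$nutrient <- attr(counts, "nutrient")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
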