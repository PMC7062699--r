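# division that returns the undefined marker (NA) on zero denominators
sdiv <- function(a, b) ifelse(b == 0, NA_real_, a / b)

#' Red-edge derivative parameters
#'
#' Computes, per sample, the red-edge position REP (wavelength of the
#' derivative maximum within the red-edge window), the derivative value
#' at that position (RES), and the summed first-derivative areas over
#' the blue edge (SDb), yellow edge (SDy) and red edge (SDr).
#'
#' Window defaults follow the common literature convention: blue edge
#' 490--530 nm, yellow edge 560--640 nm, red edge 680--760 nm; all are
#' configurable.
#'
#' @param fd a derivative `spectra_set` covering at least 490--780 nm.
#' @param windows named list of `c(lower, upper)` nm windows with
#'   elements `blue`, `yellow`, `red`.
#' @return data.frame with columns `sample_id`, `REP` (nm), `RES`
#'   (nm^-1), `SDb`, `SDy`, `SDr` (summed derivative, nm^-1 per band
#'   summed over the window).
#' @export
red_edge_params <- function(fd, windows = list(blue = c(490, 530),
                                               yellow = c(560, 640),
                                               red = c(680, 760))) {
  if (fd$kind != "derivative")
    stop("red_edge_params() expects a derivative spectra_set")
  w <- wavelengths(fd)
  for (win in names(windows)) {
    rng <- windows[[win]]
    if (rng[1] < min(w) || rng[2] > max(w))
      stop(win, "-edge window ", rng[1], "-", rng[2],
           " nm is off the derivative grid (", min(w), "-", max(w), " nm)")
  }
  in_win <- function(rng) w >= rng[1] & w <= rng[2]
  red <- in_win(windows$red)
  red_w <- w[red]
  red_vals <- fd$values[, red, drop = FALSE]
  k_max <- max.col(red_vals, ties.method = "first")
  data.frame(
    sample_id = sample_ids(fd),
    REP = red_w[k_max],
    RES = red_vals[cbind(seq_len(nrow(red_vals)), k_max)],
    SDb = rowSums(fd$values[, in_win(windows$blue), drop = FALSE]),
    SDy = rowSums(fd$values[, in_win(windows$yellow), drop = FALSE]),
    SDr = rowSums(red_vals),
    stringsAsFactors = FALSE)
}

reg_entry <- function(name, formula, citation, fun) {
  list(name = name, formula = formula, citation = citation, fun = fun)
}

#' Registry of 43 published empirical vegetation indices
#'
#' A data-driven registry of named indices from the vegetation remote-
#' sensing literature, used as the comparison baseline for the two-band
#' index scan. Each entry carries the index name, a human-readable
#' formula string, the literature citation the formula was taken from,
#' and the evaluation function itself; any entry can be replaced by the
#' user before passing the registry to [empirical_indices()], so a
#' disputed formula never silently affects the other 42.
#'
#' Evaluation functions receive three arguments: `R(nm)` and `FD(nm)`
#' returning per-sample reflectance/derivative at a band (or a mean over
#' `c(lo, hi)` when given a window), and `re`, the [red_edge_params()]
#' data.frame. Broadband "MSS" and "AVHRR" entries simulate the legacy
#' sensor bands by averaging reflectance over the band windows (the
#' upper NIR window is truncated at the 1000 nm grid limit).
#'
#' @return an object of class `index_registry`: a named list of 43
#'   entries.
#' @export
empirical_index_registry <- function() {
  nd <- function(a, b) sdiv(a - b, a + b)
  entries <- list(
    reg_entry("NDVI705", "(R750-R705)/(R750+R705)",
              "Gitelson & Merzlyak (1994)",
              function(R, FD, re) nd(R(750), R(705))),
    reg_entry("mNDVI705", "(R750-R705)/(R750+R705-2*R445)",
              "Sims & Gamon (2002)",
              function(R, FD, re)
                sdiv(R(750) - R(705), R(750) + R(705) - 2 * R(445))),
    reg_entry("mSR705", "(R750-R445)/(R705-R445)",
              "Sims & Gamon (2002)",
              function(R, FD, re) sdiv(R(750) - R(445), R(705) - R(445))),
    reg_entry("REP", "argmax of FD in 680-760 nm",
              "Horler et al. (1983)",
              function(R, FD, re) re$REP),
    reg_entry("VOG1", "R740/R720", "Vogelmann et al. (1993)",
              function(R, FD, re) sdiv(R(740), R(720))),
    reg_entry("VOG2", "(R734-R747)/(R715+R726)",
              "Vogelmann et al. (1993)",
              function(R, FD, re) sdiv(R(734) - R(747), R(715) + R(726))),
    reg_entry("VOG3", "(R734-R747)/(R715+R720)",
              "Vogelmann et al. (1993)",
              function(R, FD, re) sdiv(R(734) - R(747), R(715) + R(720))),
    reg_entry("PRI", "(R531-R570)/(R531+R570)", "Gamon et al. (1992)",
              function(R, FD, re) nd(R(531), R(570))),
    reg_entry("OSAVI", "1.16*(R800-R670)/(R800+R670+0.16)",
              "Rondeaux et al. (1996)",
              function(R, FD, re)
                sdiv(1.16 * (R(800) - R(670)), R(800) + R(670) + 0.16)),
    reg_entry("NVI", "(R777-R747)/R673", "Gupta et al. (2001)",
              function(R, FD, re) sdiv(R(777) - R(747), R(673))),
    reg_entry("NDCI", "(R708-R665)/(R708+R665)",
              "Mishra & Mishra (2012)",
              function(R, FD, re) nd(R(708), R(665))),
    reg_entry("RI1dB", "R735/R720", "Gupta et al. (2003)",
              function(R, FD, re) sdiv(R(735), R(720))),
    reg_entry("MCARI1", "1.2*(2.5*(R800-R670)-1.3*(R800-R550))",
              "Haboudane et al. (2004)",
              function(R, FD, re)
                1.2 * (2.5 * (R(800) - R(670)) - 1.3 * (R(800) - R(550)))),
    reg_entry("DVI", "R810-R680", "Jordan (1969) two-band difference",
              function(R, FD, re) R(810) - R(680)),
    reg_entry("TVIBL", "0.5*(120*(R750-R550)-200*(R670-R550))",
              "Broge & Leblanc (2000) triangular VI",
              function(R, FD, re)
                0.5 * (120 * (R(750) - R(550)) - 200 * (R(670) - R(550)))),
    reg_entry("GREEN-NDVI", "(R800-R550)/(R800+R550)",
              "Gitelson et al. (1996)",
              function(R, FD, re) nd(R(800), R(550))),
    reg_entry("Viopt", "(1+0.45)*(R800^2+1)/(R670+0.45)",
              "Reyniers et al. (2006)",
              function(R, FD, re)
                sdiv((1 + 0.45) * (R(800)^2 + 1), R(670) + 0.45)),
    reg_entry("RVI(810,560)", "R810/R560", "Xue et al. (2004)",
              function(R, FD, re) sdiv(R(810), R(560))),
    reg_entry("RVI(950,660)", "R950/R660", "Pearson & Miller (1972)",
              function(R, FD, re) sdiv(R(950), R(660))),
    reg_entry("RVI(810,660)", "R810/R660", "Pearson & Miller (1972)",
              function(R, FD, re) sdiv(R(810), R(660))),
    reg_entry("NDVI(573,440)", "(R573-R440)/(R573+R440)",
              "Stroppiana et al. (2006)",
              function(R, FD, re) nd(R(573), R(440))),
    reg_entry("FD730-525", "FD730-FD525", "Le Maire et al. (2004)",
              function(R, FD, re) FD(730) - FD(525)),
    reg_entry("FD730/525", "FD730/FD525", "Le Maire et al. (2004)",
              function(R, FD, re) sdiv(FD(730), FD(525))),
    reg_entry("FD(730-525)/(730+525)", "(FD730-FD525)/(FD730+FD525)",
              "Le Maire et al. (2004)",
              function(R, FD, re) nd(FD(730), FD(525))),
    reg_entry("FD730-570", "FD730-FD570", "Le Maire et al. (2004)",
              function(R, FD, re) FD(730) - FD(570)),
    reg_entry("FD730/570", "FD730/FD570", "Le Maire et al. (2004)",
              function(R, FD, re) sdiv(FD(730), FD(570))),
    reg_entry("FD(730-570)/(730+570)", "(FD730-FD570)/(FD730+FD570)",
              "Le Maire et al. (2004)",
              function(R, FD, re) nd(FD(730), FD(570))),
    reg_entry("FD525-570", "FD525-FD570", "Le Maire et al. (2004)",
              function(R, FD, re) FD(525) - FD(570)),
    reg_entry("FD525/570", "FD525/FD570", "Le Maire et al. (2004)",
              function(R, FD, re) sdiv(FD(525), FD(570))),
    reg_entry("FD(525–570)/(525+570)", "(FD525-FD570)/(FD525+FD570)",
              "Le Maire et al. (2004)",
              function(R, FD, re) nd(FD(525), FD(570))),
    reg_entry("MSS-DVI", "mean R 800-1000 minus mean R 600-700",
              "Tucker (1979), simulated MSS bands",
              function(R, FD, re) R(c(800, 1000)) - R(c(600, 700))),
    reg_entry("MSS-PVI",
              "(NIR-1.2*RED-0.04)/sqrt(1+1.2^2), NIR 700-800, RED 600-700",
              "Richardson & Wiegand (1977), simulated MSS bands",
              function(R, FD, re)
                (R(c(700, 800)) - 1.2 * R(c(600, 700)) - 0.04) /
                  sqrt(1 + 1.2^2)),
    reg_entry("MSS-SARVI",
              "1.5*(NIR-RB)/(NIR+RB+0.5), RB = RED-(GREEN-RED)",
              "after Kaufman & Tanre (1992), simulated MSS bands",
              function(R, FD, re) {
                nir <- R(c(700, 800)); red <- R(c(600, 700))
                rb <- red - (R(c(500, 600)) - red)
                sdiv(1.5 * (nir - rb), nir + rb + 0.5)
              }),
    reg_entry("AVHRR-GVI",
              "(NIR-RED)/(NIR+RED), RED 580-680, NIR 725-1000",
              "Kidwell (1990), simulated AVHRR bands",
              function(R, FD, re) nd(R(c(725, 1000)), R(c(580, 680)))),
    reg_entry("SDr-SDb", "SDr-SDb", "Gong et al. (2002)",
              function(R, FD, re) re$SDr - re$SDb),
    reg_entry("RES", "FD at the red-edge position",
              "Horler et al. (1983)",
              function(R, FD, re) re$RES),
    reg_entry("SDb", "sum of FD over 490-530 nm", "Gong et al. (2002)",
              function(R, FD, re) re$SDb),
    reg_entry("SDy", "sum of FD over 560-640 nm", "Gong et al. (2002)",
              function(R, FD, re) re$SDy),
    reg_entry("SDr", "sum of FD over 680-760 nm", "Gong et al. (2002)",
              function(R, FD, re) re$SDr),
    reg_entry("SDr/SDb", "SDr/SDb", "Gong et al. (2002)",
              function(R, FD, re) sdiv(re$SDr, re$SDb)),
    reg_entry("SDr/SDy", "SDr/SDy", "Gong et al. (2002)",
              function(R, FD, re) sdiv(re$SDr, re$SDy)),
    reg_entry("(SDr-SDb)/(SDr+SDb)", "(SDr-SDb)/(SDr+SDb)",
              "Gong et al. (2002)",
              function(R, FD, re) nd(re$SDr, re$SDb)),
    reg_entry("(SDr-SDy)/(SDr+SDy)", "(SDr-SDy)/(SDr+SDy)",
              "Gong et al. (2002)",
              function(R, FD, re) nd(re$SDr, re$SDy)))
  names(entries) <- vapply(entries, `[[`, "", "name")
  structure(entries, class = "index_registry")
}

#' @export
print.index_registry <- function(x, ...) {
  cat("<index_registry> ", length(x), " empirical indices\n", sep = "")
  for (e in x) cat(sprintf("  %-28s %s\n", e$name, e$formula))
  invisible(x)
}

#' Evaluate the empirical-index registry on a spectra set
#'
#' Computes every registered index for every sample. Undefined values
#' (zero denominators) propagate as `NA`.
#'
#' @param s a reflectance `spectra_set`, trimmed to within 350--1000 nm
#'   and covering the bands the registry uses (440--1000 nm).
#' @param fd optional matching derivative `spectra_set`; forward
#'   difference of `s` when omitted.
#' @param registry an [empirical_index_registry()], possibly with
#'   user-overridden entries.
#' @return data.frame, one row per sample (`sample_id` first column),
#'   one column per index, names exactly as registered.
#' @export
empirical_indices <- function(s, fd = NULL,
                              registry = empirical_index_registry()) {
  if (s$kind != "reflectance")
    stop("empirical_indices() expects reflectance input")
  if (!is_trimmed(s))
    stop("spectra extend outside 350-1000 nm; apply trim_spectra() first")
  if (is.null(fd)) fd <- first_derivative(s)
  getter <- function(set) function(nm) {
    if (length(nm) == 2L) {
      w <- wavelengths(set)
      keep <- w >= nm[1] & w <= nm[2]
      if (!any(keep)) stop("window ", nm[1], "-", nm[2], " nm off grid")
      rowMeans(set$values[, keep, drop = FALSE])
    } else {
      set$values[, band_col(set, nm), drop = TRUE]
    }
  }
  Rf <- getter(s); FDf <- getter(fd)
  re <- red_edge_params(fd)
  out <- data.frame(sample_id = sample_ids(s), stringsAsFactors = FALSE)
  for (e in registry) out[[e$name]] <- as.numeric(e$fun(Rf, FDf, re))
  out
}

#' Serialize an index registry to YAML
#'
#' Writes the registry metadata (name, formula string, citation) so the
#' exact formula set used in an analysis is recorded alongside its
#' outputs. Functions are not serialized; the YAML is a provenance
#' record, not an executable form.
#'
#' @param registry an [empirical_index_registry()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_index_registry <- function(registry, path) {
  meta <- lapply(unname(registry), function(e)
    list(name = e$name, formula = e$formula, citation = e$citation))
  yaml::write_yaml(meta, path)
  invisible(path)
}
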