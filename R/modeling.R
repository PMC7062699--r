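#' Adjusted coefficient of determination
#'
#' @param r2 unadjusted R-squared in [0, 1].
#' @param n number of fitted observations.
#' @param k number of predictor terms (excluding the intercept).
#' @return 1 - (1 - r2) * (n - 1) / (n - k - 1).
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

new_nutrient_model <- function(nutrient, intercept, terms, fit_r2 = NA,
                               adj_r2 = NA, n_fit = NA, model_p = NA,
                               id = NULL, provenance = "fitted",
                               empty = FALSE) {
  structure(list(id = id, nutrient = nutrient, intercept = intercept,
                 terms = terms, fit_r2 = fit_r2, adj_r2 = adj_r2,
                 n_fit = n_fit, model_p = model_p,
                 provenance = provenance, empty = empty),
            class = "nutrient_model")
}

#' @export
print.nutrient_model <- function(x, digits = 4, ...) {
  rhs <- if (nrow(x$terms) == 0) "" else
    paste0(" ", paste(sprintf("%+g*%s", x$terms$coefficient,
                              x$terms$label), collapse = " "))
  cat("<nutrient_model> ", x$nutrient, " = ", format(x$intercept),
      rhs, "\n", sep = "")
  if (is.finite(x$fit_r2))
    cat("  fit R2 = ", round(x$fit_r2, digits), ", adjusted R2 = ",
        round(x$adj_r2, digits), ", n = ", x$n_fit, "\n", sep = "")
  if (x$empty) cat("  [empty: no candidate passed the entry threshold]\n")
  invisible(x)
}

#' Stepwise multiple linear regression
#'
#' Greedy forward-entry / backward-removal variable selection for a
#' leaf-nutrient response over spectral-index candidate predictors. At
#' each step the candidate with the smallest partial-F p-value is
#' entered if that p-value is at most `entry_p`; after every entry, any
#' included term whose partial-F p-value exceeds `removal_p` is removed
#' (worst first). The loop terminates when no entry occurs. Candidates
#' that are perfectly collinear with the current model are skipped and
#' reported. Rows containing any missing candidate value are dropped
#' listwise before fitting and the remaining count is reported as
#' `n_fit`.
#'
#' @param X data.frame or matrix of candidate predictors, columns
#'   named by term (e.g. `"D_500_600"`).
#' @param y numeric nutrient response aligned with the rows of `X`.
#' @param entry_p largest partial-F p-value at which a candidate may
#'   enter (default 0.05).
#' @param removal_p partial-F p-value above which an included term is
#'   removed (default 0.10); must be >= `entry_p` to preclude cycling.
#' @param nutrient optional label stored on the model.
#' @param term_info optional data.frame (`label`, `family`, `bands`)
#'   describing each candidate; matched rows are carried into the
#'   model's term table.
#' @return a `nutrient_model` with `intercept`, a `terms` table
#'   (label, family, bands, coefficient, p), `fit_r2`, `adj_r2`,
#'   `model_p` (overall F-test), `n_fit` and `r2_trace` (the fit
#'   R-squared after each entry step). When nothing enters, the
#'   intercept-only model is returned flagged `empty`.
#' @export
stepwise_fit <- function(X, y, entry_p = 0.05, removal_p = 0.10,
                         nutrient = NULL, term_info = NULL) {
  X <- as.data.frame(X)
  if (!nrow(X) || is.null(names(X)) || any(names(X) == ""))
    stop("X must be a named predictor table")
  if (length(y) != nrow(X)) stop("y must align with the rows of X")
  if (removal_p < entry_p)
    stop("removal_p must be >= entry_p to avoid entry/removal cycling")
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 3L) stop("fewer than 3 complete rows after listwise deletion")

  candidates <- names(X)
  included <- character(0)
  design <- function(terms) cbind(`(Intercept)` = 1,
                                  as.matrix(X[, terms, drop = FALSE]))
  partial_p <- function(fit, label) {
    cf <- summary(fit)$coefficients
    if (!label %in% rownames(cf)) return(NA_real_)
    cf[label, "Pr(>|t|)"]
  }
  fit_terms <- function(terms) {
    df <- data.frame(.y = y, X[, terms, drop = FALSE], check.names = FALSE)
    stats::lm(.y ~ ., data = df)
  }

  r2_trace <- numeric(0)
  tss <- sum((y - mean(y))^2)
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    # an (essentially) exact fit leaves no residual scale, so further
    # partial-F p-values are numerical noise: stop entering
    if (length(included) &&
        sum(stats::resid(fit_terms(included))^2) <= 1e-10 * tss) break
    base_rank <- qr(design(included))$rank
    entry <- vapply(pool, function(cand) {
      if (qr(design(c(included, cand)))$rank <= base_rank) {
        message("skipping '", cand,
                "': collinear with the current model")
        return(NA_real_)
      }
      partial_p(fit_terms(c(included, cand)), make.names(cand))
    }, numeric(1))
    if (all(is.na(entry)) || min(entry, na.rm = TRUE) > entry_p) break
    included <- c(included, pool[which.min(entry)])
    # backward pass: drop worst offender until all terms satisfy removal_p
    repeat {
      fit <- fit_terms(included)
      ps <- vapply(included, function(tm) partial_p(fit, make.names(tm)),
                   numeric(1))
      if (!length(ps) || max(ps, na.rm = TRUE) <= removal_p) break
      included <- included[-which.max(ps)]
    }
    r2_trace <- c(r2_trace, summary(fit_terms(included))$r.squared)
  }

  if (!length(included)) {
    terms <- data.frame(label = character(0), family = character(0),
                        bands = character(0), coefficient = numeric(0),
                        p = numeric(0), stringsAsFactors = FALSE)
    return(new_nutrient_model(nutrient %||% NA_character_, mean(y),
                              terms, fit_r2 = 0, adj_r2 = 0, n_fit = n,
                              model_p = NA_real_, empty = TRUE))
  }
  fit <- fit_terms(included)
  sm <- summary(fit)
  cf <- sm$coefficients
  k <- length(included)
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  lookup <- function(label, col) {
    if (is.null(term_info)) return(NA_character_)
    i <- match(label, term_info$label)
    if (is.na(i)) NA_character_ else as.character(term_info[[col]][i])
  }
  terms <- data.frame(
    label = included,
    family = vapply(included, lookup, "", col = "family"),
    bands = vapply(included, lookup, "", col = "bands"),
    coefficient = cf[make.names(included), "Estimate"],
    p = cf[make.names(included), "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  out <- new_nutrient_model(nutrient %||% NA_character_,
                            cf["(Intercept)", "Estimate"], terms,
                            fit_r2 = sm$r.squared,
                            adj_r2 = adjusted_r2(sm$r.squared, n, k),
                            n_fit = n, model_p = unname(model_p))
  out$r2_trace <- r2_trace
  out
}

#' Predict leaf nutrient content from a model
#'
#' Evaluates intercept + sum(coefficient * predictor) exactly. Every
#' term of the model must be supplied by name; an absent predictor is
#' an error naming the term, never a silent zero.
#'
#' @param object a `nutrient_model` (fitted or from
#'   [published_models()]).
#' @param newdata named numeric vector, list or data.frame of predictor
#'   values keyed by term label (e.g. `D_937`).
#' @param ... unused.
#' @return numeric vector of nutrient estimates (mg g-1).
#' @export
predict.nutrient_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.list(newdata)
  missing <- setdiff(object$terms$label, names(newdata))
  if (length(missing))
    stop("missing predictor value(s) for term(s): ",
         paste(missing, collapse = ", "))
  out <- rep(object$intercept,
             max(1L, if (nrow(object$terms)) length(newdata[[
               object$terms$label[1]]]) else 1L))
  for (i in seq_len(nrow(object$terms)))
    out <- out + object$terms$coefficient[i] *
      newdata[[object$terms$label[i]]]
  out
}

#' Build a candidate predictor table from selected bands
#'
#' Turns a set of sensitive wavelengths into the predictor columns a
#' stepwise fit consumes: for one-band families the value at each band,
#' for two-band families the index at every unordered band pair
#' (i < j, the pair evaluated as (i, j)). Column names encode family
#' and band(s), e.g. `R_700`, `D_500_600`.
#'
#' @param x a trimmed reflectance `spectra_set`.
#' @param family family name (see [index_families()]).
#' @param bands integer wavelengths (nm) to combine.
#' @param fd optional matching derivative `spectra_set`.
#' @return list with `X` (data.frame of predictors) and `info`
#'   (data.frame `label`, `family`, `bands`).
#' @export
predictor_table <- function(x, family, bands, fd = NULL) {
  info <- family_info(family)
  bands <- sort(unique(as.integer(bands)))
  X <- list(); labels <- character(0); bstr <- character(0)
  if (info$arity == 1L) {
    for (b in bands) {
      lab <- paste0(family, "_", b)
      X[[lab]] <- unname(pair_index(family, x, i = b, fd = fd))
      labels <- c(labels, lab); bstr <- c(bstr, as.character(b))
    }
  } else {
    if (length(bands) < 2L) stop("two-band family needs >= 2 bands")
    prs <- utils::combn(bands, 2)
    for (c0 in seq_len(ncol(prs))) {
      i <- prs[1, c0]; j <- prs[2, c0]
      lab <- paste0(family, "_", i, "_", j)
      X[[lab]] <- unname(pair_index(family, x, i = i, j = j, fd = fd))
      labels <- c(labels, lab); bstr <- c(bstr, paste0(i, "/", j))
    }
  }
  list(X = as.data.frame(X, check.names = FALSE),
       info = data.frame(label = labels, family = family, bands = bstr,
                         stringsAsFactors = FALSE))
}

#' Validate predictions against observed values
#'
#' Ordinary least squares of predicted on observed (the conventional
#' predicted-vs-field scatter), reporting slope, intercept, R-squared
#' and the two-sided p-value of the slope. The transpose regression is
#' available via `direction`.
#'
#' @param predicted,observed aligned numeric vectors (n >= 3).
#' @param direction `"predicted_on_observed"` (default) or
#'   `"observed_on_predicted"`.
#' @return an object of class `validation_report`: list with `slope`,
#'   `intercept`, `r2`, `p`, `n`, `direction`.
#' @export
validate_predictions <- function(predicted, observed,
                                 direction = c("predicted_on_observed",
                                               "observed_on_predicted")) {
  direction <- match.arg(direction)
  if (length(predicted) != length(observed)) stop("vectors must align")
  keep <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[keep]; observed <- observed[keep]
  if (length(observed) < 3L) stop("need at least 3 aligned pairs")
  xv <- if (direction == "predicted_on_observed") observed else predicted
  yv <- if (direction == "predicted_on_observed") predicted else observed
  if (stats::var(xv) == 0) stop("zero variance in the regressor")
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = sm$coefficients["xv", "Pr(>|t|)"],
                 n = length(yv), direction = direction),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$direction, ": slope = ",
      signif(x$slope, 4), ", intercept = ", signif(x$intercept, 4),
      ", R2 = ", signif(x$r2, 4), ", p = ", format.pval(x$p),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Serialize a nutrient model to JSON
#'
#' @param model a `nutrient_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a nutrient model from JSON
#'
#' @param path JSON path written by [write_model()].
#' @return a `nutrient_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- as.data.frame(obj$terms, stringsAsFactors = FALSE)
  new_nutrient_model(obj$nutrient, obj$intercept, terms,
                     fit_r2 = obj$fit_r2 %||% NA_real_,
                     adj_r2 = obj$adj_r2 %||% NA_real_,
                     n_fit = obj$n_fit %||% NA_integer_,
                     model_p = obj$model_p %||% NA_real_,
                     id = obj$id, provenance = obj$provenance %||% "file",
                     empty = isTRUE(obj$empty))
}
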