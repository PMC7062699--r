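test_that("adjusted_r2 follows the closed form", {
  expect_equal(adjusted_r2(1, 30, 4), 1)
  expect_equal(adjusted_r2(0, 11, 1), -1 / 9)
  expect_equal(adjusted_r2(0.876, 64, 3), 0.8698, tolerance = 1e-4)
  expect_error(adjusted_r2(0.5, 4, 3), "must exceed")
})

test_that("stepwise keeps a planted signal and drops noise", {
  set.seed(31)
  n <- 30
  x1 <- rnorm(n)
  X <- data.frame(x1 = x1)
  for (k in 2:10) X[[paste0("x", k)]] <- rnorm(n)
  y <- 2 + 3 * x1
  m <- stepwise_fit(X, y, nutrient = "N")
  expect_identical(m$terms$label, "x1")
  expect_equal(m$intercept, 2, tolerance = 1e-8)
  expect_equal(m$terms$coefficient, 3, tolerance = 1e-8)
  expect_gt(m$fit_r2, 0.999)
  expect_false(m$empty)
})

test_that("pure noise yields the flagged intercept-only model", {
  set.seed(32)
  X <- as.data.frame(matrix(rnorm(40 * 6), 40,
                            dimnames = list(NULL, paste0("x", 1:6))))
  y <- rnorm(40)
  m <- stepwise_fit(X, y, entry_p = 1e-6)
  expect_true(m$empty)
  expect_identical(nrow(m$terms), 0L)
  expect_equal(m$intercept, mean(y))
})

test_that("exact duplicates trigger the collinearity guard", {
  set.seed(33)
  x1 <- rnorm(40)
  X <- data.frame(x1 = x1, dup = x1, x2 = rnorm(40))
  y <- 1 + 2 * x1 + rnorm(40, 0, 0.1)
  expect_message(m <- stepwise_fit(X, y), "collinear")
  expect_identical(sum(m$terms$label %in% c("x1", "dup")), 1L)
})

test_that("stepwise reproduces an independent greedy oracle", {
  set.seed(34)
  for (rep in 1:8) {
    n <- 25 + rep
    X <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("v", 1:6))))
    beta <- c(2, -1.5, 0, 0, 0, 0)[sample(6)]
    y <- as.matrix(X) %*% beta + rnorm(n, 0, 0.5)
    m <- stepwise_fit(X, y)
    expect_identical(m$terms$label,
                     oracle_stepwise(X, y), info = paste("rep", rep))
  }
})

test_that("stepwise termination conditions hold on random instances", {
  set.seed(35)
  for (rep in 1:6) {
    n <- 40
    X <- as.data.frame(matrix(rnorm(n * 8), n,
                              dimnames = list(NULL, paste0("v", 1:8))))
    y <- 1 + rowSums(X[, 1:2]) * 1.5 + rnorm(n)
    m <- stepwise_fit(X, y, entry_p = 0.05, removal_p = 0.10)
    if (nrow(m$terms)) {
      # retained terms all satisfy the removal criterion
      expect_true(all(m$terms$p <= 0.10))
      # excluded candidates all fail the entry criterion
      excl <- setdiff(names(X), m$terms$label)
      df <- data.frame(.y = y, X[, m$terms$label, drop = FALSE],
                       check.names = FALSE)
      for (cand in excl) {
        df2 <- df; df2[[cand]] <- X[[cand]]
        fit <- lm(.y ~ ., data = df2)
        pc <- summary(fit)$coefficients
        expect_gt(pc[make.names(cand), "Pr(>|t|)"], 0.05)
      }
      # fit R2 is non-decreasing across entry steps
      expect_true(all(diff(m$r2_trace) >= -1e-12))
    }
  }
})

test_that("rows with undefined markers are dropped listwise", {
  set.seed(36)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  X$a[c(3, 7)] <- NA
  y <- 2 * X$b + rnorm(20, 0, 0.1)
  m <- stepwise_fit(X, y)
  expect_identical(m$n_fit, 18L)
})

test_that("predict evaluates the printed equations exactly", {
  reg <- published_models()
  expect_length(reg, 21L)
  d_n <- reg[["D_N"]]
  zeros <- setNames(as.list(numeric(nrow(d_n$terms))), d_n$terms$label)
  expect_identical(predict(d_n, zeros), 21.6)
  nd_k <- reg[["ND_K"]]
  zk <- setNames(as.list(numeric(3)), nd_k$terms$label)
  expect_identical(predict(nd_k, zk), 61.47)
  # unit increment recovers each coefficient exactly
  unit <- zeros; unit[["D_937"]] <- 1
  expect_identical(predict(d_n, unit) - predict(d_n, zeros), -2186.079)
  # missing predictor errors by term name
  expect_error(predict(d_n, zeros[-1]), "D_937")
})

test_that("predict is exactly linear", {
  m <- published_model("FD_N")
  v <- setNames(as.list(c(0.01, -0.02, 0.005)), m$terms$label)
  zero <- setNames(as.list(numeric(3)), m$terms$label)
  av <- lapply(v, function(z) 3 * z)
  expect_equal(predict(m, av) - predict(m, zero),
               3 * (predict(m, v) - predict(m, zero)), tolerance = 1e-12)
})

test_that("published registry coefficients survive serialization bit-exactly", {
  reg <- published_models()
  raw <- jsonlite::read_json(system.file("extdata",
                                         "published_models.json",
                                         package = "nutrispec"),
                             simplifyVector = FALSE)
  for (m in raw$stepwise) {
    got <- reg[[m$id]]
    expect_identical(got$intercept, m$intercept, info = m$id)
    expect_identical(got$terms$coefficient,
                     vapply(m$terms, `[[`, 0, "coefficient"),
                     info = m$id)
  }
  # round trip through the model JSON writer
  f <- tempfile(fileext = ".json")
  write_model(reg[["FDD_P"]], f)
  back <- read_model(f)
  expect_identical(back$intercept, reg[["FDD_P"]]$intercept)
  expect_identical(back$terms$coefficient,
                   reg[["FDD_P"]]$terms$coefficient)
})

test_that("single-index published equations evaluate as printed", {
  res_k <- published_model("RES_K")
  expect_identical(predict(res_k, list(RES = 0)), 131.48)
  expect_identical(predict(res_k, list(RES = 1)) -
                     predict(res_k, list(RES = 0)), -7846.6)
})

test_that("validation regression reports slope, intercept, r2, p", {
  obs <- c(18, 20, 22, 25, 19, 21)
  rep1 <- validate_predictions(obs, obs)
  expect_equal(rep1$slope, 1)
  expect_equal(rep1$intercept, 0, tolerance = 1e-12)
  expect_equal(rep1$r2, 1)
  rep2 <- validate_predictions(2 * obs + 5, obs)
  expect_equal(rep2$slope, 2, tolerance = 1e-12)
  expect_equal(rep2$intercept, 5, tolerance = 1e-9)
  # r2 equals squared Pearson correlation
  set.seed(37)
  pred <- obs <- rnorm(20, 20, 3)
  pred <- pred + rnorm(20)
  rep3 <- validate_predictions(pred, obs)
  expect_equal(rep3$r2, cor(pred, obs)^2, tolerance = 1e-12)
  expect_error(validate_predictions(rnorm(5), rep(1, 5)),
               "zero variance")
  # transpose direction exposed by flag
  rep4 <- validate_predictions(pred, obs,
                               direction = "observed_on_predicted")
  expect_equal(rep4$r2, rep3$r2, tolerance = 1e-12)
})

test_that("predictor_table builds labelled family columns", {
  s <- window_spectra(trim_spectra(full_range_set(0.2, n = 5)), 500, 510)
  set.seed(38)
  s$values <- matrix(runif(55, 0.1, 0.5), 5, 11,
                     dimnames = dimnames(s$values))
  pt <- predictor_table(s, "D", c(500, 505, 510))
  expect_identical(names(pt$X), c("D_500_505", "D_500_510", "D_505_510"))
  expect_equal(pt$X$D_500_505,
               unname(pair_index("D", s, i = 500, j = 505)))
  pt1 <- predictor_table(s, "R", c(500, 510))
  expect_identical(names(pt1$X), c("R_500", "R_510"))
  expect_identical(pt$info$bands[1], "500/505")
})
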