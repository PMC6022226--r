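# Activity transforms, OLS fitting with LOO statistics, residual and
# validation bookkeeping.

test_that("pIC50 is -log10 of the micromolar IC50", {
  expect_equal(round(pic50(3.48), 4), -0.5416)
  expect_equal(pic50(1), 0)
  expect_equal(round(pic50(192.69), 4), -2.2849)
  expect_error(pic50(NA), "censored")
  expect_error(pic50(-1), "positive")
})

test_that("OLS recovers a noiseless linear model exactly", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 2 * X[, 1] - 3
  fit <- fit_mlr(X, y)
  expect_equal(fit$model$intercept, -3, tolerance = 1e-10)
  expect_equal(unname(fit$model$terms), c(2, 0), tolerance = 1e-10)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-10)
})

test_that("fit_mlr rejects degenerate inputs informatively", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_mlr(X[1:3, ], rnorm(3)), "more samples")
  Xc <- X; Xc[, 2] <- 5
  expect_error(fit_mlr(Xc, rnorm(10)), "constant.*b")
  Xd <- X; Xd[, 3] <- 2 * X[, 1]
  expect_error(fit_mlr(Xd, rnorm(10)), "collinear")
})

test_that("leverage-based PRESS equals the refit-n-times oracle", {
  set.seed(3)
  for (k in 1:20) {
    n <- sample(10:25, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("d", 1:p)))
    y <- rnorm(n) + X[, 1]
    fit <- fit_mlr(X, y)
    expect_equal(fit$stats$press, refit_press(X, y), tolerance = 1e-9)
  }
})

test_that("q2 <= r2 and PRESS >= SSE on 100 seeded fits; r2 is squared Pearson", {
  set.seed(4)
  for (k in 1:100) {
    n <- sample(12:30, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("d", 1:p)))
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = runif(1, 0.1, 2))
    fit <- fit_mlr(X, y)
    expect_gte(fit$stats$press, fit$stats$sse)
    expect_lte(fit$stats$q2_loo, fit$stats$r2)
    expect_equal(fit$stats$r2, cor(y, fit$fitted)^2, tolerance = 1e-9)
  }
})

test_that("adjusted r2 identity reproduces both printed pairs", {
  expect_equal(round(adjusted_r2(0.940, 13, 4), 3), 0.910)
  expect_equal(round(adjusted_r2(0.896, 14, 3), 3), 0.865)
})

test_that("prediction from fixed models is the linear form", {
  pm <- published_models()
  zero <- data.frame(CHI_3_C = 0, Dipole_Y = 0, Jurs_PNSA_3 = 0,
                     Shadow_YZ = 0)
  expect_equal(predict(pm$HepG2, zero), -0.7926)
  row2 <- data.frame(IAC_Mean = 1, Dipole_X = 0, Shadow_Ylength = 0)
  expect_equal(predict(pm[["Caco-2"]], row2), -6.6095 - 3.7896)
  expect_error(predict(pm$HepG2, row2), "CHI_3_C")

  # self-consistency: predict() reproduces the fitted values of fit_mlr
  set.seed(5)
  X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- drop(X %*% c(1, -1, 2)) + rnorm(15, sd = 0.1)
  fit <- fit_mlr(X, y)
  expect_equal(predict(fit$model, as.data.frame(X)), fit$fitted,
               tolerance = 1e-10)
})

test_that("residual tables reproduce the printed bookkeeping", {
  rt <- residual_table(c(`4b` = -1.8253), c(`4b` = -2.0638))
  expect_equal(rt$residual, 0.2385)
  same <- residual_table(c(a = 1.5, b = -2), c(a = 1.5, b = -2))
  expect_equal(same$residual, c(0, 0))
  expect_error(residual_table(c(a = 1), c(b = 1)), "labels")
  expect_error(residual_table(1.2, 1.2), "named")
})

test_that("selectivity index and fold change match the printed assays", {
  expect_equal(round(selectivity_index(73.20, 3.48)), 21)
  expect_equal(round(selectivity_index(55.92, 5.03)), 11)
  expect_equal(selectivity_index(7, 7), 1)
  expect_error(selectivity_index(-1, 2), "positive")

  expect_equal(round(fold_change(453.3, 27.52), 1), 16.5)
  expect_equal(round(fold_change(0.3021, 0.0457), 1), 6.6)
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("external validation refuses train/test overlap and applies the model", {
  desc <- data.frame(CHI_3_C = c(1, 2), Dipole_Y = c(0, 1),
                     Jurs_PNSA_3 = c(-10, -20), Shadow_YZ = c(50, 60),
                     row.names = c("t1", "t2"))
  act <- c(t1 = -1, t2 = -2)
  pm <- published_models()
  expect_error(external_validate(pm$HepG2, desc, act,
                                 train_labels = c("t2", "x")), "t2")
  rt <- external_validate(pm$HepG2, desc, act, train_labels = "other")
  expect_equal(rt$predicted,
               unname(predict(pm$HepG2, desc)), tolerance = 1e-12)

  flat <- qsar_model("any", 0.5, c(CHI_3_C = 0))
  rt2 <- external_validate(flat, desc, act)
  expect_equal(rt2$residual, unname(act) - 0.5)
})

test_that("the training split matches the outlier listing", {
  hep <- training_split("HepG2")
  expect_setequal(hep$test, c("6", "8d", "15a", "15c"))
  expect_length(hep$train, 13)
  caco <- training_split("Caco-2")
  expect_setequal(caco$test, c("6", "9", "11a"))
  expect_length(caco$train, 14)
  expect_length(intersect(hep$train, hep$test), 0)
})

test_that("model JSON round-trips", {
  m <- qsar_model("HepG2", -0.7926,
                  c(CHI_3_C = -1.598, Dipole_Y = 0.2775))
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$terms, m$terms)
})
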