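# Activity conversion, MLR fitting/validation, descriptor selection,
# the frozen published model.

test_that("pIC50 conversion follows the molar convention and round-trips", {
  expect_equal(pic50FromIC50(1), 9.0)
  expect_equal(pic50FromIC50(1000), 6.0)
  expect_equal(pic50FromIC50(5), 9 - log10(5), tolerance = 1e-12)
  expect_equal(round(pic50FromIC50(5), 3), 8.301)
  # the 5-300 nM training range maps onto pIC50 [6.523, 8.301]
  expect_equal(round(pic50FromIC50(300), 3), 6.523)
  x <- c(0.3, 5, 2500, 1e6)
  expect_equal(ic50FromPic50(pic50FromIC50(x)), x, tolerance = 1e-9)
  expect_error(pic50FromIC50(0), "positive")
  expect_error(pic50FromIC50(-5), "positive")
})

test_that("per-compound averaging converts before taking the mean", {
  one <- data.frame(compound_id = "a", ic50_nM = 100)
  expect_equal(meanPic50(one), 7.0)
  four <- data.frame(compound_id = "a", isoform = c("HDAC1", "HDAC2",
                                                    "HDAC3", "HDAC8"),
                     ic50_nM = rep(10, 4))
  expect_equal(meanPic50(four), 8.0)
  mix <- data.frame(compound_id = "a", ic50_nM = c(10, 100, 100, 1000))
  expect_equal(meanPic50(mix), 7.0)
  expect_error(meanPic50(data.frame(compound_id = c("a", "b"),
                                    ic50_nM = c(1, 2))), "single compound")
})

test_that("activity classification uses the 2500 nM threshold, tie to decoy", {
  expect_equal(classifyActivity(2400), "active")
  expect_equal(classifyActivity(2600), "decoy")
  expect_equal(classifyActivity(2500), "decoy")
  # a 71-compound design with 41 sub-threshold IC50s yields the 41/30 split
  ic50 <- c(seq(5, 2400, length.out = 41), seq(2600, 50000, length.out = 30))
  lab <- classifyActivity(ic50)
  expect_equal(sum(lab == "active"), 41L)
  expect_equal(sum(lab == "decoy"), 30L)
})

test_that("fitMLR recovers an exact line and matches the SVD oracle", {
  x <- 1:5
  fit <- suppressWarnings(fitMLR(data.frame(x = x), 2 + 3 * x))
  expect_equal(unname(fit@coefficients), c(2, 3), tolerance = 1e-9)
  expect_equal(fit@r2, 1, tolerance = 1e-9)

  set.seed(11)
  for (rep in 1:100) {
    n <- sample(8:15, 1); p <- sample(2:3, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n,
                              dimnames = list(NULL, paste0("d", 1:p))))
    y <- rnorm(n)
    fit <- fitMLR(X, y)
    expect_equal(unname(fit@coefficients), unname(oracleOLS(X, y)),
                 tolerance = 1e-8)
    # residuals of an intercept model sum to zero
    expect_equal(sum(fit@residuals), 0, tolerance = 1e-9)
    expect_lte(fit@adj_r2, fit@r2 + 1e-12)
  }
})

test_that("fitMLR rejects under-determined and rank-deficient designs", {
  X <- data.frame(a = rnorm(4), b = rnorm(4), c = rnorm(4))
  expect_error(fitMLR(X, rnorm(4)), "n > p")
  set.seed(2)
  Xr <- data.frame(a = rnorm(10))
  Xr$b <- 2 * Xr$a
  expect_error(fitMLR(Xr, rnorm(10)), "rank deficient.*b")
})

test_that("adjusted R2 reproduces the printed statistics pair", {
  expect_equal(adjustedR2(0.93, n = 10, p = 5), 0.8425, tolerance = 1e-12)
  expect_equal(round(adjustedR2(0.93, 10, 5), 2), 0.84)
})

test_that("the frozen published model carries the printed constants", {
  pm <- publishedModel()
  expect_equal(unname(pm@coefficients),
               c(14.48, -0.13, 0.06, 0.17, -2.54, -2.57))
  expect_equal(unname(pm@se), c(3.8, 0.06, 0.04, 0.04, 0.5, 1.21))
  expect_length(pm@coefficients[-1], 5L)
  expect_equal(pm@n, 10L)
  expect_equal(pm@r2, 0.93)
  expect_equal(pm@adj_r2, 0.84)
  expect_equal(pm@see, 0.24)
  expect_equal(pm@p_value, 0.02)
  # the implied overall F is consistent with the printed p-value
  sig <- anovaSignificance(pm)
  expect_equal(sig$p, 0.02, tolerance = 0.005)
})

test_that("prediction is the linear form over named descriptors", {
  pm <- publishedModel()
  zero <- c(mol_polarizability = 0, logp = 0, tpsa = 0, hba = 0,
            balaban_j = 0)
  expect_equal(predictPic50(pm, zero), 14.48)
  hand <- c(mol_polarizability = 30, logp = 2, tpsa = 60, hba = 4,
            balaban_j = 2)
  expect_equal(predictPic50(pm, hand), 5.60, tolerance = 1e-9)
  expect_error(predictPic50(pm, c(logp = 1)), "missing")
})

test_that("external validation reports residuals, flags and external R2", {
  set.seed(5)
  X <- data.frame(x = rnorm(50))
  y <- 1 + 2 * X$x
  fit <- suppressWarnings(fitMLR(X, y))
  v <- externalValidate(fit, X, y)
  expect_equal(v$table$residual, rep(0, 50), tolerance = 1e-9)
  expect_equal(v$external_r2, 1, tolerance = 1e-12)
  expect_equal(v$n_flagged, 0L)

  # constant-prediction model has external R2 = 0
  cm <- new("QSARModel",
            coefficients = c("(Intercept)" = mean(y), x = 0),
            se = c("(Intercept)" = 0, x = 0), n = 50L, r2 = 0,
            adj_r2 = 0, see = 0, f_stat = NA_real_, p_value = NA_real_,
            residuals = numeric(0))
  expect_equal(externalValidate(cm, X, y)$external_r2, 0, tolerance = 1e-12)

  # noisy case matches a direct sum-of-squares oracle
  yn <- y + rnorm(50, 0, 0.2)
  fitn <- fitMLR(X, yn)
  vn <- externalValidate(fitn, X, yn)
  pred <- fitn@coefficients[1] + fitn@coefficients[2] * X$x
  r2_oracle <- 1 - sum((yn - pred)^2) / sum((yn - mean(yn))^2)
  expect_equal(vn$external_r2, r2_oracle, tolerance = 1e-9)
  expect_error(externalValidate(fitn, X, yn[-1]), "length")
})

test_that("forward selection finds a planted strong predictor", {
  set.seed(21)
  n <- 40
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- 5 + 10 * X$signal + rnorm(n, 0, 1)   # 10-sigma effect
  for (method in c("FS", "SS")) {
    sel <- selectDescriptors(X, y, method = method)
    expect_true("signal" %in% sel$selected)
    expect_false(any(c("noise1", "noise2") %in% sel$selected))
  }
  # exhaustive check: 'signal' alone is the best single-column model
  r2s <- vapply(names(X), function(cn)
    fitMLR(X[, cn, drop = FALSE], y)@r2, numeric(1))
  expect_equal(names(which.max(r2s)), "signal")
})

test_that("backward elimination keeps a fully informative model intact", {
  set.seed(9)
  n <- 30
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X$a - 3 * X$b + rnorm(n, 0, 0.05)
  sel <- selectDescriptors(X, y, method = "BE")
  expect_setequal(sel$selected, c("a", "b"))
})

test_that("selection under the null is approximately at the nominal rate", {
  picked <- 0L
  for (s in 1:40) {
    set.seed(3000 + s)
    X <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
    y <- rnorm(100)
    sel <- suppressWarnings(selectDescriptors(X, y, method = "FS"))
    if (length(sel$selected)) picked <- picked + 1L
  }
  # ~5% per-column false-entry rate, 3 columns -> loose bound of 25%
  expect_lte(picked / 40, 0.25)
})

test_that("ANOVA F agrees with explicit sums of squares and null p is uniform-ish", {
  set.seed(13)
  X <- data.frame(a = rnorm(25), b = rnorm(25))
  y <- 1 + X$a + rnorm(25, 0, 0.5)
  fit <- fitMLR(X, y)
  sig <- anovaSignificance(fit)
  pred <- predictPic50(fit, X)
  ssr <- sum((pred - mean(y))^2); sse <- sum((y - pred)^2)
  f_oracle <- (ssr / 2) / (sse / (25 - 2 - 1))
  expect_equal(sig$F, f_oracle, tolerance = 1e-9)

  # perfect fit: p reported as (numerically) zero
  fit0 <- suppressWarnings(fitMLR(data.frame(x = 1:8), 2 * (1:8) + 1))
  expect_lt(anovaSignificance(fit0)$p, 1e-12)

  # under the null the p-value distribution is roughly uniform
  ps <- vapply(1:60, function(s) {
    set.seed(7000 + s)
    Xn <- data.frame(a = rnorm(30))
    anovaSignificance(fitMLR(Xn, rnorm(30)))$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.5), 0.75)
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(17)
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  fit <- fitMLR(X, rnorm(12))
  path <- withr::local_tempfile()
  writeQSARModel(fit, path)
  back <- readQSARModel(path)
  expect_identical(back@coefficients, fit@coefficients)
  expect_identical(back@se, fit@se)
  expect_identical(back@residuals, fit@residuals)
  expect_identical(back@r2, fit@r2)
})

test_that("parameter recovery from the frozen coefficients is within 3 SE", {
  co <- publishedModel()@coefficients
  terms <- names(co)[-1]
  # noiseless: exact identification
  cfg0 <- simulationConfig(n_compounds = 60, seed = 3, noise_sd = 0)
  act0 <- simulateActivities(generateLibrary(cfg0), cfg0)
  fit0 <- suppressWarnings(fitMLR(act0[, terms], act0$pic50))
  expect_equal(fit0@coefficients, co, tolerance = 1e-8)
  # sigma = 0.24, n = 200: each coefficient within 3 estimated SE
  cfg <- simulationConfig(n_compounds = 200, seed = 7, noise_sd = 0.24)
  act <- simulateActivities(generateLibrary(cfg), cfg)
  fit <- fitMLR(act[, terms], act$pic50)
  expect_true(all(abs(fit@coefficients - co) <= 3 * fit@se))
})
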