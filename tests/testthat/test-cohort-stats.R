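test_that("OLS fits recover exact relationships and edge cases", {
  x <- 1:10
  f <- fitLinear(2 * x + 1, cbind(x = x))
  expect_equal(unname(f@coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(f@r2, 1)
  fc <- fitLinear(rep(3.5, 12), cbind(x = rnorm(12)))
  expect_equal(fc@r2, 0)
  expect_error(fitLinear(rnorm(10), cbind(a = 1:10, b = 2 * (1:10))),
               "rank-deficient.*b")
})

test_that("coefficients match the normal-equations oracle and R base AIC", {
  # small fixed dataset, multivariate
  y <- c(4.1, 6.9, 7.3, 11.8, 13.2)
  X <- cbind(x1 = c(1, 2, 3, 4, 5), x2 = c(0.3, -0.2, 0.5, 0.1, -0.4))
  f <- fitLinear(y, X)
  M <- cbind(1, X)
  beta <- solve(t(M) %*% M, t(M) %*% y)  # brute-force normal equations
  expect_equal(unname(f@coefficients), unname(drop(beta)), tolerance = 1e-10)
  lmfit <- lm(y ~ X)
  expect_equal(f@aic, stats::AIC(lmfit), tolerance = 1e-9)
  expect_equal(f@r2, summary(lmfit)$r.squared, tolerance = 1e-12)
  # univariate: R^2 equals the squared Pearson correlation; p from slope t
  set.seed(17)
  x <- rnorm(40); yy <- 1 + 0.7 * x + rnorm(40)
  fu <- fitLinear(yy, cbind(x = x))
  expect_equal(fu@r2, cor(x, yy)^2, tolerance = 1e-10)
  su <- summary(lm(yy ~ x))$coefficients
  expect_equal(fu@pValue, su["x", "Pr(>|t|)"], tolerance = 1e-12)
  expect_equal(fu@slopeSE, su["x", "Std. Error"], tolerance = 1e-12)
})

test_that("backward stepwise agrees with exhaustive AIC search", {
  set.seed(107)
  n <- 100
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 3 + 5 * X[, "x1"] + rnorm(n)
  st <- backwardStepwiseAIC(y, X)
  expect_identical(st$selected, "x1")
  expect_identical(sort(st$selected), sort(exhaustiveAIC(y, X)$selected))

  # three mutually correlated overlap-like predictors; x1 carries the
  # signal, mirroring the collapse of the overlap family to one variable
  set.seed(1107)
  z <- rnorm(n)
  Xc <- cbind(x1 = z + 0.2 * rnorm(n), x2 = z + 0.6 * rnorm(n),
              x3 = z + 0.6 * rnorm(n))
  yc <- 10 + 20 * Xc[, "x1"] + rnorm(n, sd = 2)
  stc <- backwardStepwiseAIC(yc, Xc)
  expect_identical(stc$selected, "x1")
  expect_identical(sort(stc$selected), sort(exhaustiveAIC(yc, Xc)$selected))
})

test_that("all-noise predictors collapse to the intercept-only model", {
  # pure noise: stepwise should agree with the exhaustive subset search,
  # which picks the empty model at this seed
  set.seed(211)
  n <- 100
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  ynoise <- rnorm(n)
  expect_length(exhaustiveAIC(ynoise, X)$selected, 0L)
  st0 <- backwardStepwiseAIC(ynoise, X)
  expect_length(st0$selected, 0L)
  expect_lte(st0$fit@aic, fitLinear(ynoise, X)@aic)
})

test_that("stepwise always ends at a single-deletion local minimum", {
  set.seed(202)
  for (rep in 1:10) {
    n <- 60
    X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
    beta <- ifelse(runif(4) < 0.5, 0, runif(4, -2, 2))
    y <- drop(1 + X %*% beta + rnorm(n))
    st <- backwardStepwiseAIC(y, X)
    full <- fitLinear(y, X)
    expect_lte(st$fit@aic, full@aic)
    for (v in st$selected) {
      without <- fitLinear(y, X[, setdiff(st$selected, v), drop = FALSE])
      expect_gte(without@aic, st$fit@aic)
    }
  }
})

test_that("ROC follows the strict-> threshold convention", {
  rc <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(auc(rc), 0.75)  # 3 of 4 positive-negative pairs ordered
  expect_equal(rc@sensitivity[1], 1); expect_equal(rc@specificity[1], 0)
  k <- length(rc@thresholds)
  expect_equal(rc@sensitivity[k], 0); expect_equal(rc@specificity[k], 1)

  sep <- rocCurve(c(1, 2, 3, 10, 11), c(F, F, F, T, T))
  expect_equal(auc(sep), 1.0)
  tied <- rocCurve(rep(0.5, 6), c(T, F, T, F, F, T))
  expect_equal(auc(tied), 0.5)
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "both outcome classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(auc(rocCurve(scores, labels)),
                 pairCountAUC(scores, labels), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(auc(rocCurve(exp(2 * scores), labels)),
                 auc(rocCurve(scores, labels)), tolerance = 1e-12)
  }
})

test_that("operating point maximizes Youden J with smallest-threshold ties", {
  rc <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  op <- optimalOperatingPoint(rc)
  expect_equal(op@threshold, 0.225)  # tie with J = 0.5 at 0.6 resolved down
  expect_equal(op@sensitivity, 1.0)
  expect_equal(op@specificity, 0.5)
  expect_equal(op@youdenJ, 0.5)

  sep <- rocCurve(c(1, 2, 3, 10, 11), c(F, F, F, T, T))
  ops <- optimalOperatingPoint(sep)
  expect_equal(ops@threshold, 6.5)  # midpoint between the classes
  expect_equal(ops@youdenJ, 1.0)

  # adding a constant shifts the threshold, not the performance
  sc <- c(0.1, 0.4, 0.35, 0.8)
  op2 <- optimalOperatingPoint(rocCurve(sc + 3, c(F, F, T, T)))
  expect_equal(op2@threshold, op@threshold + 3)
  expect_equal(c(op2@sensitivity, op2@specificity),
               c(op@sensitivity, op@specificity))

  opc <- optimalOperatingPoint(sep, criterion = "closest01")
  expect_equal(opc@threshold, 6.5)
})

test_that("slope inference is unbiased with nominal CI coverage", {
  set.seed(404)
  b <- 1.8
  nrep <- 1000
  hits <- 0
  est <- numeric(nrep)
  for (r in seq_len(nrep)) {
    x <- rnorm(30)
    y <- 2 + b * x + rnorm(30, sd = 1.5)
    f <- fitLinear(y, cbind(x = x))
    est[r] <- f@coefficients[2]
    half <- qt(0.975, df = 28) * f@slopeSE
    hits <- hits + (abs(f@coefficients[2] - b) <= half)
  }
  expect_lt(abs(mean(est) - b), 0.02)
  expect_gte(hits / nrep, 0.92)
  expect_lte(hits / nrep, 0.98)
})
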