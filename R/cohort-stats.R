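## Regression, backward stepwise AIC selection, and ROC machinery used to
## compare overlap predictors and calibrate the decision threshold.

#' Ordinary least squares fit with a fixed AIC convention
#'
#' Fits y ~ 1 + X by OLS. The reported AIC uses the full Gaussian
#' log-likelihood with the error variance counted as a parameter,
#' \deqn{AIC = n\log(2\pi) + n\log(RSS/n) + n + 2(p + 2),}
#' matching mainstream statistics software, so stepwise selection here is
#' comparable with standard tools. The two-sided slope-t p-value is reported
#' for single-predictor fits (NA otherwise). For a constant outcome (zero
#' total sum of squares) R^2 is defined as 0.
#'
#' @param y numeric outcome vector
#' @param X numeric predictor matrix (0 or more named columns); a plain
#'   vector is treated as one column
#' @return a \linkS4class{RegressionFit}
#' @examples
#' x <- 1:10
#' fitLinear(2 * x + 1, cbind(x = x))
#' @export
fitLinear <- function(y, X) {
  if (is.null(dim(X))) X <- cbind(x = X)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (p > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(p))
  if (p > 0 && nrow(X) != n) stop("y and X disagree in length")
  if (n < p + 2L) stop("need n >= p + 2 observations")
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dep <- colnames(M)[qrM$pivot[-seq_len(qrM$rank)]]
    stop("rank-deficient predictor matrix; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  coef <- qr.coef(qrM, y)
  res <- y - drop(M %*% coef)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  r2 <- min(max(r2, 0), 1)
  aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * (p + 2)
  pval <- NA_real_
  se <- NA_real_
  if (p == 1L && rss > 0) {
    sigma2 <- rss / (n - 2L)
    sxx <- sum((X[, 1L] - mean(X[, 1L]))^2)
    se <- sqrt(sigma2 / sxx)
    tstat <- coef[2L] / se
    pval <- 2 * stats::pt(abs(tstat), df = n - 2L, lower.tail = FALSE)
  }
  new("RegressionFit", predictors = colnames(X) %||% character(),
      coefficients = coef, r2 = r2, pValue = unname(pval),
      slopeSE = unname(se), aic = aic, n = as.integer(n))
}

#' Backward stepwise variable selection by AIC
#'
#' Starts from the full model and at each step removes the single variable
#' whose removal lowers AIC the most, stopping when no removal lowers AIC.
#' The intercept is never removed. Ties between equally good removals are
#' broken by removing the lexicographically last name, so the procedure is
#' deterministic.
#'
#' @param y numeric outcome vector
#' @param X numeric predictor matrix with named columns
#' @return \code{list(selected = <names>, fit = <RegressionFit of the final
#'   model>, trace = <data.frame of step, removed, aic>)}
#' @export
backwardStepwiseAIC <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  current <- colnames(X)
  fit <- fitLinear(y, X[, current, drop = FALSE])
  trace <- data.frame(step = 0L, removed = "(full model)", aic = fit@aic,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    cand <- vapply(current, function(v) {
      fitLinear(y, X[, setdiff(current, v), drop = FALSE])@aic
    }, numeric(1))
    best <- min(cand)
    if (!(best < fit@aic)) break
    tied <- names(cand)[cand <= best + 1e-10]
    drop1 <- sort(tied)[length(tied)]
    current <- setdiff(current, drop1)
    fit <- fitLinear(y, X[, current, drop = FALSE])
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = drop1,
                                     aic = fit@aic,
                                     stringsAsFactors = FALSE))
  }
  list(selected = current, fit = fit, trace = trace)
}

#' ROC curve of a score against a binary outcome
#'
#' Candidate thresholds are -Inf, the midpoints between consecutive distinct
#' sorted scores, and +Inf. A case is called positive when its score is
#' strictly greater than the threshold (so the curve runs from
#' (sensitivity 1, specificity 0) at -Inf to (0, 1) at +Inf). AUC is the
#' trapezoidal area over (1 - specificity, sensitivity), which equals the
#' Mann-Whitney pair statistic with ties counted one half.
#'
#' @param scores numeric predictor scores
#' @param labels logical (or 0/1) outcome; TRUE = positive
#' @return a \linkS4class{RocCurve}
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be equal-length and free of NA")
  nP <- sum(labels)
  nN <- sum(!labels)
  if (nP == 0L || nN == 0L)
    stop(sprintf(
      "ROC needs both outcome classes (got %d positive, %d negative)",
      nP, nN))
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  sens <- vapply(thr, function(t) sum(scores > t & labels) / nP, numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & !labels) / nN,
                 numeric(1))
  fpr <- 1 - spec  # decreasing in threshold order
  k <- length(thr)
  aucv <- sum(-diff(fpr) * (sens[-1L] + sens[-k]) / 2)
  new("RocCurve", thresholds = thr, sensitivity = sens, specificity = spec,
      auc = aucv)
}

#' Optimal operating point of a ROC curve
#'
#' Chooses the threshold that best trades sensitivity against specificity.
#' The default criterion maximizes the Youden index J = sensitivity +
#' specificity - 1; \code{"closest01"} instead minimizes the Euclidean
#' distance to the perfect corner (sensitivity 1, specificity 1). Ties are
#' resolved toward the smallest threshold — the highest-sensitivity choice,
#' conservative for toxicity screening.
#'
#' @param rc a \linkS4class{RocCurve}
#' @param criterion "youden" (default) or "closest01"
#' @return an \linkS4class{OperatingPoint}
#' @export
optimalOperatingPoint <- function(rc, criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  stopifnot(is(rc, "RocCurve"))
  score <- switch(criterion,
    youden = rc@sensitivity + rc@specificity - 1,
    closest01 = -sqrt((1 - rc@sensitivity)^2 + (1 - rc@specificity)^2))
  best <- which(score >= max(score) - 1e-12)
  i <- best[which.min(rc@thresholds[best])]
  new("OperatingPoint", threshold = rc@thresholds[i],
      sensitivity = rc@sensitivity[i], specificity = rc@specificity[i],
      youdenJ = rc@sensitivity[i] + rc@specificity[i] - 1)
}
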