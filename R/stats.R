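#' Logistic-regression lesion classifier
#'
#' Maximum-likelihood logistic regression of lesion class on E/B
#' features, fit by iteratively reweighted least squares on standardized
#' features with a small ridge penalty on the slopes (the intercept is
#' unpenalized).  The ridge guarantees finite, deterministic
#' coefficients under complete separation.
#'
#' @param x numeric matrix or data frame of features (rows = lesion-view
#'   records).
#' @param y class labels: logical, or factor/character with positive
#'   class `"malignant"`.
#' @param ridge ridge penalty on standardized slopes (default `1e-6`).
#' @param max_iter,tol IRLS iteration controls.
#' @return An object of class `visr_logistic` with standardized and
#'   raw-scale coefficients.
#' @export
fit_logistic <- function(x, y, ridge = 1e-6, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_positive_class(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 2) stop("need at least 2 rows per class")
  stopifnot(nrow(x) == length(y), ridge >= 0)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  X <- cbind(`(intercept)` = 1, xs)
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  slopes_raw <- beta[-1] / scl
  coef_raw <- c(beta[1] - sum(slopes_raw * ctr), slopes_raw)
  names(coef_raw) <- c("(intercept)", colnames(x) %||%
                         paste0("x", seq_len(ncol(x))))
  structure(list(coef_std = beta, coef_raw = coef_raw,
                 center = ctr, scale = scl, iterations = it,
                 ridge = ridge, n = nrow(x)),
            class = "visr_logistic")
}

as_positive_class <- function(y) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) return(as.numeric(y == "malignant"))
  as.numeric(y)
}

#' @export
predict.visr_logistic <- function(object, newdata, ...) {
  X <- cbind(1, scale(as.matrix(newdata), center = object$center,
                      scale = object$scale))
  drop(X %*% object$coef_std)
}

#' ROC analysis of classifier scores
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance of
#' scores (rank statistic with tie correction), with sensitivity and
#' specificity reported at the Youden-optimal operating point
#' (maximizing sensitivity + specificity - 1).
#'
#' @param scores numeric classifier scores (higher = more malignant).
#' @param labels class labels (see [fit_logistic()]).
#' @return An object of class `visr_roc`: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `curve` (data frame), `n`,
#'   `degenerate`.
#' @export
roc_analysis <- function(scores, labels) {
  y <- as_positive_class(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  degenerate <- length(unique(scores)) < 2
  if (degenerate) {
    return(structure(list(auc = 0.5, sensitivity = 1, specificity = 0,
                          threshold = unique(scores)[1],
                          curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                          n = length(y), degenerate = TRUE),
                     class = "visr_roc"))
  }
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  cand <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(scores[y == 1] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[y == 0] <= t), numeric(1))
  youden <- sens + spec - 1
  k <- which.max(youden)
  curve <- data.frame(fpr = 1 - spec, tpr = sens)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  structure(list(auc = auc, sensitivity = sens[k], specificity = spec[k],
                 threshold = cand[k], curve = curve, n = length(y),
                 degenerate = FALSE),
            class = "visr_roc")
}

#' Correlation with significance test
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (!all(is.finite(y))) stop("y contains non-finite values")
  if (stats::sd(x) == 0) stop("x is constant (zero variance)")
  if (stats::sd(y) == 0) stop("y is constant (zero variance)")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 10 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b numeric samples.
#' @return A list `statistic` (rank-sum W of `a`), `p`, `exact`.
#' @export
ranksum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  use_exact <- (length(a) + length(b) <= 10) &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       exact = use_exact)
}
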