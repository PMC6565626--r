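#' @title Logistic prediction and evaluation
#' @description Fit binary logistic models on linguistic predictors; compute
#'   Wald tests, decision boundaries, confusion metrics and train/holdout
#'   transfer.
#' @name prediction
NULL

#' Construct a logistic model from known coefficients
#'
#' Wraps coefficients (and optionally standard errors) in the model object
#' used throughout the evaluation layer — useful for evaluating a published
#' regression equation on new data.
#'
#' @param coefficients named numeric vector; first element the intercept
#'   (named `(Intercept)` if unnamed).
#' @param standard_errors optional numeric vector aligned with `coefficients`.
#' @param converged,separation flags carried in diagnostics.
#' @param log_likelihood optional.
#' @export
logistic_model <- function(coefficients, standard_errors = NULL,
                           converged = TRUE, separation = FALSE,
                           log_likelihood = NA_real_) {
  if (is.null(names(coefficients)) || !nzchar(names(coefficients)[1]))
    names(coefficients)[1] <- "(Intercept)"
  if (is.null(standard_errors))
    standard_errors <- rep(NA_real_, length(coefficients))
  stopifnot(length(standard_errors) == length(coefficients))
  structure(list(coefficients = coefficients,
                 standard_errors = setNames(standard_errors,
                                            names(coefficients)),
                 predictor_names = names(coefficients)[-1],
                 converged = converged, separation = separation,
                 log_likelihood = log_likelihood),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  eq <- paste(sprintf("%+.4f", x$coefficients[-1]), "*",
              x$predictor_names, collapse = " ")
  cat("<logistic_model> logit(p) = ", sprintf("%.4f ", x$coefficients[1]), eq,
      if (x$separation) "  [separation: ridge-penalized]", "\n", sep = "")
  invisible(x)
}

# ridge-penalized IRLS (penalty on slopes, not the intercept); returns
# coefficients and standard errors from the penalized information matrix
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  Pen <- diag(c(0, rep(2 * lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + Pen
    g <- crossprod(X, y - mu) - Pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(crossprod(X, X * plogis(drop(X %*% beta)) *
                                    (1 - plogis(drop(X %*% beta)))) + Pen)))
  mu <- plogis(drop(X %*% beta))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coefficients = beta, se = se, loglik = ll)
}

#' Fit a binary logistic model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (`stats::glm`). Quasi-complete separation — fitted probabilities pinned to
#' 0/1 together with diverging coefficients — is detected and handled by
#' refitting with a small ridge penalty (`lambda = 1e-4` on the slopes),
#' flagged in the returned model.
#'
#' @param features data.frame (or named numeric vector for one predictor) of
#'   per-participant predictor values; no missing values.
#' @param labels binary outcomes (0/1 or logical), both classes present with
#'   at least two observations each.
#' @param ridge_lambda penalty used by the separation fallback.
#' @return a [logistic_model()].
#' @export
fit_logistic <- function(features, labels, ridge_lambda = 1e-4) {
  if (is.numeric(features) && is.null(dim(features)))
    features <- data.frame(x = features)
  features <- as.data.frame(features)
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(features) == length(y))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 participants per class")
  if (anyNA(features)) stop("missing predictor values")

  fml <- stats::as.formula(paste("y ~", paste(names(features), collapse = " + ")))
  dat <- cbind(features, y = y)
  fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
  mu <- fitted(fit)
  sep <- any(mu < 1e-6 | mu > 1 - 1e-6) &&
    (max(abs(coef(fit))) > 50 || !fit$converged)
  if (!sep && fit$converged) {
    sm <- summary(fit)
    return(logistic_model(coef(fit), sm$coefficients[, "Std. Error"],
                          converged = TRUE, separation = FALSE,
                          log_likelihood = as.numeric(stats::logLik(fit))))
  }
  if (!sep && !fit$converged)
    stop("logistic fit failed to converge without detectable separation")
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  rf <- ridge_logistic(X, y, lambda = ridge_lambda)
  logistic_model(setNames(rf$coefficients, colnames(X)),
                 rf$se, converged = TRUE, separation = TRUE,
                 log_likelihood = rf$loglik)
}

#' Predicted conversion probabilities
#'
#' @param object a [logistic_model()].
#' @param features data.frame with the model's predictors (or numeric vector
#'   for a single-predictor model).
#' @param ... unused.
#' @export
predict.logistic_model <- function(object, features, ...) {
  if (is.numeric(features) && is.null(dim(features)))
    features <- setNames(data.frame(features), object$predictor_names)
  features <- as.data.frame(features)
  miss <- setdiff(object$predictor_names, names(features))
  if (length(miss))
    stop("holdout features lack predictor(s): ", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(features[object$predictor_names]))
  plogis(drop(X %*% object$coefficients))
}

#' Wald chi-square test for one predictor
#'
#' `(coefficient / standard error)^2` on one degree of freedom.
#'
#' @param model a [logistic_model()] with standard errors.
#' @param predictor predictor name (default: the single predictor).
#' @return list: `statistic`, `p_value`.
#' @export
wald_chi2 <- function(model, predictor = NULL) {
  predictor <- predictor %||% {
    if (length(model$predictor_names) != 1)
      stop("specify the predictor for a multi-predictor model")
    model$predictor_names
  }
  if (!predictor %in% names(model$coefficients)) stop("unknown predictor: ", predictor)
  b <- model$coefficients[[predictor]]
  se <- model$standard_errors[[predictor]]
  if (is.na(se) || se == 0) stop("standard error unavailable or zero")
  stat <- (b / se)^2
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Decision boundary of a single-predictor model
#'
#' The predictor value at which the predicted probability is 0.5:
#' `-intercept / slope`.
#'
#' @param model a single-predictor [logistic_model()] with nonzero slope.
#' @export
decision_boundary <- function(model) {
  if (length(model$predictor_names) != 1)
    stop("decision boundary is defined for single-predictor models")
  slope <- model$coefficients[[2]]
  if (slope == 0) stop("zero slope: no decision boundary")
  -model$coefficients[[1]] / slope
}

#' Confusion matrix and derived metrics
#'
#' Counts true/false positives/negatives and derives accuracy, precision,
#' recall (sensitivity), specificity and F1. Ratios with zero denominators
#' are reported as `NA` (undefined), never as 0.
#'
#' @param predicted,actual equal-length binary vectors (0/1 or logical).
#' @return list of class `confusion_metrics`.
#' @export
confusion_metrics <- function(predicted, actual) {
  p <- as.numeric(predicted); a <- as.numeric(actual)
  if (length(p) != length(a)) stop("predicted and actual differ in length")
  if (!length(p)) stop("need at least one item")
  stopifnot(all(p %in% c(0, 1)), all(a %in% c(0, 1)))
  tp <- sum(p == 1 & a == 1); fp <- sum(p == 1 & a == 0)
  tn <- sum(p == 0 & a == 0); fn <- sum(p == 0 & a == 1)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(p),
                 precision = precision, recall = recall,
                 specificity = ratio(tn, tn + fp), f1 = f1),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> tp=%d fp=%d tn=%d fn=%d | acc=%.3f prec=%s rec=%s spec=%s f1=%s\n",
              x$tp, x$fp, x$tn, x$fn, x$accuracy,
              format(round(x$precision, 3)), format(round(x$recall, 3)),
              format(round(x$specificity, 3)), format(round(x$f1, 3))))
  invisible(x)
}

#' Apply a trained model to holdout data
#'
#' Classifies holdout observations at the probability `threshold` using the
#' training coefficients and returns confusion metrics.
#'
#' @param model a [logistic_model()].
#' @param features holdout predictor values (matching the model's predictors).
#' @param labels holdout binary outcomes.
#' @param threshold probability cutoff (default 0.5); observations with
#'   predicted probability `>= threshold` are classified positive.
#' @export
evaluate_transfer <- function(model, features, labels, threshold = 0.5) {
  prob <- predict(model, features)
  confusion_metrics(as.numeric(prob >= threshold), labels)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y equal-length numeric vectors (n >= 3, nonzero variances).
#' @return list: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# rank-based AUC of scores for binary labels (probability a positive scores
# above a negative, ties counted half)
auc_score <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("AUC needs both classes")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
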