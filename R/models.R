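#' Linear model specifications for the classification harness
#'
#' A model spec bundles a `fit(x, y, weights)` function returning a fitted
#' object and a `decision(fit, x)` function returning real-valued scores
#' (positive predicts class 1). Two specs ship with the package; any list
#' with the same shape plugs into [cv_evaluate()] and
#' [train_final_model()].
#'
#' `model_spec_svm_l1()` is an L1-regularized linear support vector
#' machine: it minimizes `||w||_1 + C * sum_i s_i * max(0, 1 - y_i f_i)^2`
#' (squared hinge, primal, intercept unpenalized) by FISTA proximal
#' gradient with backtracking. `class_weight = "balanced"` sets the sample
#' weights `s_i` inversely proportional to class frequencies.
#'
#' `model_spec_logistic()` is an L1-penalized logistic regression fitted
#' with glmnet at a fixed penalty.
#'
#' @param C inverse regularization strength on the loss term (default 0.1).
#' @param class_weight `NULL` or `"balanced"`.
#' @param max_iter,tol solver budget and relative-change stopping
#'   tolerance.
#' @return object of class `bitome_model_spec`.
#' @export
model_spec_svm_l1 <- function(C = 0.1, class_weight = NULL,
                              max_iter = 2000L, tol = 1e-7) {
  structure(list(
    name = "svm_l1",
    params = list(C = C, class_weight = class_weight),
    fit = function(x, y, weights = NULL) {
      s <- sample_weights(y, weights, class_weight)
      fit_svm_l1(x, y, C = C, weights = s, max_iter = max_iter, tol = tol)
    },
    decision = function(fit, x) drop(x %*% fit$w + fit$b)
  ), class = "bitome_model_spec")
}

#' @rdname model_spec_svm_l1
#' @param lambda glmnet L1 penalty (default 0.01).
#' @export
model_spec_logistic <- function(lambda = 0.01, class_weight = NULL) {
  structure(list(
    name = "logistic_l1",
    params = list(lambda = lambda, class_weight = class_weight),
    fit = function(x, y, weights = NULL) {
      s <- sample_weights(y, weights, class_weight)
      # glmnet needs >= 2 columns and some variance; pad constant matrices
      fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                            alpha = 1, lambda = lambda, weights = s,
                            standardize = FALSE)
      list(w = as.numeric(fit$beta), b = as.numeric(fit$a0), glmnet = fit,
           converged = TRUE)
    },
    decision = function(fit, x) drop(x %*% fit$w + fit$b)
  ), class = "bitome_model_spec")
}

#' @noRd
sample_weights <- function(y, weights, class_weight) {
  if (!is.null(weights)) return(weights)
  if (identical(class_weight, "balanced")) {
    n <- length(y)
    tab <- table(factor(y, levels = c(0, 1)))
    w <- n / (2 * pmax(as.numeric(tab), 1))
    unname(w[as.character(y)])
  } else {
    rep(1, length(y))
  }
}

#' FISTA solver for the L1 + squared-hinge objective
#'
#' Minimizes `||w||_1 + C * sum_i s_i * max(0, 1 - y_i (x_i w + b))^2`
#' over `(w, b)` with the intercept unpenalized. Accelerated proximal
#' gradient with backtracking line search; soft-thresholding is the
#' proximal operator of the L1 term.
#'
#' @param x numeric matrix (samples x features).
#' @param y labels in `{0, 1}`.
#' @param C loss weight.
#' @param weights per-sample weights.
#' @param max_iter,tol iteration budget and relative objective tolerance.
#' @return list `w`, `b`, `converged`, `objective`, `iterations`.
#' @export
fit_svm_l1 <- function(x, y, C = 0.1, weights = rep(1, length(y)),
                       max_iter = 2000L, tol = 1e-7) {
  x <- as.matrix(x)
  ypm <- ifelse(y == 1, 1, -1)
  n <- nrow(x); p <- ncol(x)
  smooth <- function(w, b) {
    h <- pmax(0, 1 - ypm * (drop(x %*% w) + b))
    C * sum(weights * h^2)
  }
  grad <- function(w, b) {
    f <- drop(x %*% w) + b
    h <- pmax(0, 1 - ypm * f)
    g <- -2 * C * weights * h * ypm
    list(w = drop(crossprod(x, g)), b = sum(g))
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  w <- numeric(p); b <- 0
  zw <- w; zb <- b
  t_mom <- 1
  step <- 1 / max(1e-8, 2 * C * max(weights) * (sum(x^2) / n + 1))
  obj_old <- smooth(w, b) + sum(abs(w))
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    g <- grad(zw, zb)
    f_z <- smooth(zw, zb)
    repeat {
      w_new <- soft(zw - step * g$w, step)
      b_new <- zb - step * g$b
      dw <- w_new - zw; db <- b_new - zb
      lhs <- smooth(w_new, b_new)
      rhs <- f_z + sum(g$w * dw) + g$b * db + (sum(dw^2) + db^2) / (2 * step)
      if (lhs <= rhs + 1e-12 || step < 1e-14) break
      step <- step / 2
    }
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    zw <- w_new + (t_mom - 1) / t_new * (w_new - w)
    zb <- b_new + (t_mom - 1) / t_new * (b_new - b)
    w <- w_new; b <- b_new; t_mom <- t_new
    obj <- smooth(w, b) + sum(abs(w))
    if (abs(obj_old - obj) <= tol * max(1, abs(obj_old))) { converged <- TRUE; break }
    obj_old <- obj
  }
  if (!converged) {
    warn(sprintf("svm_l1 solver did not converge in %d iterations (last objective %.6g)",
                 max_iter, obj_old))
  }
  list(w = w, b = b, converged = converged,
       objective = smooth(w, b) + sum(abs(w)), iterations = it)
}
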