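# Linear maximum-margin classifier (primal L2-regularized squared-hinge SVM).
# No SVM library is assumed; the problem sizes here (<= ~400 patterns x 70
# voxels) make a BFGS solve of the smooth primal both fast and deterministic.

#' Fit a linear maximum-margin classifier
#'
#' Minimizes `0.5 ||w||^2 + C * sum(max(0, 1 - y f(x))^2)` with
#' `f(x) = x.w + b` and an unpenalized intercept; the squared hinge keeps the
#' objective differentiable so a quasi-Newton solve is exact enough for a
#' maximum-margin separator. Labels are coerced to -1/+1 in factor-level
#' order.
#'
#' @param x Numeric matrix, rows = observations.
#' @param y Two-class labels (factor, character or -1/+1 numeric).
#' @param C Regularization constant (default 1).
#' @return A `linear_svm`: list with `w`, `b`, `levels`.
#' @export
svm_linear <- function(x, y, C = 1) {
  x <- as.matrix(x)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("need exactly two classes", call. = FALSE)
  ys <- ifelse(as.integer(yf) == 1, -1, 1)
  d <- ncol(x)
  xe <- cbind(x, 1)                        # extended design; intercept last
  reg <- c(rep(1, d), 0)                   # intercept unpenalized
  obj <- function(par, xi) 0.5 * sum(reg * par^2) + C * sum(xi^2)
  par <- numeric(d + 1)
  xi <- pmax(0, 1 - ys * drop(xe %*% par))
  f_cur <- obj(par, xi)
  # damped Newton on the piecewise-quadratic objective: exact Hessian on the
  # active set, halving line search; converges in a handful of iterations
  for (iter in 1:50) {
    g <- reg * par - 2 * C * drop(crossprod(xe, ys * xi))
    if (sqrt(sum(g^2)) < 1e-8 * (1 + abs(f_cur))) break
    act <- xi > 0
    H <- diag(reg + 1e-10, d + 1) +
      2 * C * crossprod(xe[act, , drop = FALSE])
    step <- solve(H, g)
    alpha <- 1
    repeat {
      par_new <- par - alpha * step
      xi_new <- pmax(0, 1 - ys * drop(xe %*% par_new))
      f_new <- obj(par_new, xi_new)
      if (f_new <= f_cur || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (f_cur - f_new < 1e-10 * (1 + abs(f_cur))) {
      par <- par_new; xi <- xi_new; f_cur <- f_new
      break
    }
    par <- par_new; xi <- xi_new; f_cur <- f_new
  }
  structure(list(w = par[seq_len(d)], b = par[d + 1],
                 levels = levels(yf)), class = "linear_svm")
}

#' Predict class labels from a linear_svm
#' @param object A `linear_svm`.
#' @param newdata Numeric matrix of observations.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- drop(as.matrix(newdata) %*% object$w) + object$b
  object$levels[ifelse(f >= 0, 2, 1)]
}
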