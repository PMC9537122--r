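# Kernel evaluation between row-matrices A and B.
.svm_kernel <- function(A, B, kernel, gamma) {
  switch(kernel,
    linear = A %*% t(B),
    gaussian = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      exp(-gamma * pmax(d2, 0))
    },
    cubic = (A %*% t(B) + 1)^3,
    stop("unknown kernel: ", kernel)
  )
}

#' Fit a soft-margin support vector machine
#'
#' Solves the dual problem
#' `min 1/2 a' Q a - e' a` subject to `0 <= a <= C`, `y' a = 0`
#' (with `Q = (y y') * K`) by sequential minimal optimization over
#' maximally violating pairs.  Convergence is declared when the
#' feasibility gap between the primal and dual objective, relative to
#' `1 + |primal|`, falls below `tol`.  Kernels: `"linear"`,
#' `"gaussian"` (parameter `gamma`), and `"cubic"`, the polynomial kernel
#' `(x . x' + 1)^3`.
#'
#' @param X training features (rows = segments).
#' @param y class labels; anesthesia is the positive class (+1).
#' @param C box constraint (> 0).
#' @param kernel kernel name.
#' @param gamma Gaussian-kernel width (default `1/ncol(X)`).
#' @param tol feasibility-gap tolerance (default 1e-3).
#' @param max_iter maximum pair updates before aborting with an error.
#' @param standardize standardize features by training mean/sd.
#' @return an object of class `ppg_svm` holding the support vectors,
#'   dual coefficients `alpha`, bias `b`, and for the linear kernel the
#'   primal normal `beta` on the original feature scale.
#' @export
svm_fit <- function(X, y, C = 1, kernel = c("linear", "gaussian", "cubic"),
                    gamma = NULL, tol = 1e-3, max_iter = 100000,
                    standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as_anes_label(y)
  stopifnot(nrow(X) == length(y), C > 0)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  std <- .standardizer(X, standardize)
  Xs <- .apply_standardizer(std, X)
  ysgn <- ifelse(y == "anesthesia", 1, -1)
  n <- nrow(Xs)
  K <- .svm_kernel(Xs, Xs, kernel, gamma)
  Q <- (ysgn %o% ysgn) * K
  alpha <- numeric(n)
  G <- rep(-1, n)  # gradient of the dual objective: Q a - e
  eps_kkt <- 1e-12
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("SVM failed to converge in ", max_iter,
           " iterations (gap tolerance ", tol, ")")
    }
    # maximal violating pair (LIBSVM working-set selection)
    up <- (ysgn == 1 & alpha < C - eps_kkt) | (ysgn == -1 & alpha > eps_kkt)
    lo <- (ysgn == 1 & alpha > eps_kkt) | (ysgn == -1 & alpha < C - eps_kkt)
    if (!any(up) || !any(lo)) break
    f <- -ysgn * G
    i <- which(up)[which.max(f[up])]
    j <- which(lo)[which.min(f[lo])]
    m_up <- f[i]; m_lo <- f[j]
    if (m_up - m_lo < 1e-8) break
    if (m_up - m_lo < 1e-5 && .svm_gap(alpha, G, ysgn, C) < tol) break
    # analytic step t along alpha_i' = alpha_i + y_i t,
    # alpha_j' = alpha_j - y_j t (preserves y' a = 0)
    quad <- Q[i, i] + Q[j, j] - 2 * ysgn[i] * ysgn[j] * Q[i, j]
    if (quad <= 0) quad <- 1e-12
    head_i <- if (ysgn[i] == 1) C - alpha[i] else alpha[i]
    head_j <- if (ysgn[j] == 1) alpha[j] else C - alpha[j]
    step <- min((m_up - m_lo) / quad, head_i, head_j)
    if (step <= 0) break
    dai <- ysgn[i] * step
    daj <- -ysgn[j] * step
    alpha[i] <- alpha[i] + dai
    alpha[j] <- alpha[j] + daj
    G <- G + Q[, i] * dai + Q[, j] * daj
    if (iter %% 50L == 0L && .svm_gap(alpha, G, ysgn, C) < tol) break
  }
  # bias from the KKT conditions: average -y*G over free vectors, else
  # midpoint of the feasible interval
  f <- -ysgn * G
  free <- alpha > eps_kkt & alpha < C - eps_kkt
  b <- if (any(free)) {
    mean(f[free])
  } else {
    up <- (ysgn == 1 & alpha < C - eps_kkt) | (ysgn == -1 & alpha > eps_kkt)
    lo <- (ysgn == 1 & alpha > eps_kkt) | (ysgn == -1 & alpha < C - eps_kkt)
    if (!any(up) || !any(lo)) 0 else (max(f[up]) + min(f[lo])) / 2
  }
  sv <- alpha > eps_kkt
  beta <- NULL
  if (kernel == "linear") {
    beta_std <- colSums(Xs * (alpha * ysgn))
    # back-transform to the original feature scale
    beta <- beta_std / std$scale
    b_raw <- b - sum(beta_std * std$center / std$scale)
  } else {
    b_raw <- NULL
  }
  structure(
    list(kernel = kernel, gamma = gamma, C = C, tol = tol,
         sv = Xs[sv, , drop = FALSE], alpha = alpha[sv],
         ysgn = ysgn[sv], b = b, beta = beta, b_raw = b_raw,
         std = std, n_iter = iter, features = colnames(X)),
    class = "ppg_svm"
  )
}

# Feasibility gap between primal and dual objectives, relative to the
# primal magnitude.  dual = e'a - 1/2 a'Qa; primal = 1/2 a'Qa + C * hinge,
# using (Qa)_i = G_i + 1 and y_i f(x_i) = (Qa)_i + y_i b.
.svm_gap <- function(alpha, G, ysgn, C) {
  aQa <- sum(alpha * (G + 1))
  dual <- sum(alpha) - 0.5 * aQa
  fval <- -ysgn * G
  free <- alpha > 1e-12 & alpha < C - 1e-12
  b <- if (any(free)) mean(fval[free]) else {
    upm <- (ysgn == 1 & alpha < C - 1e-12) | (ysgn == -1 & alpha > 1e-12)
    lom <- (ysgn == 1 & alpha > 1e-12) | (ysgn == -1 & alpha < C - 1e-12)
    if (!any(upm) || !any(lom)) 0 else (max(fval[upm]) + min(fval[lom])) / 2
  }
  yf <- (G + 1) + ysgn * b
  primal <- 0.5 * aQa + C * sum(pmax(0, 1 - yf))
  (primal - dual) / (1 + abs(primal))
}

#' Predict with an SVM model
#'
#' Decision value `f(x) = sum_j alpha_j y_j K(x_j, x) + b`; the label is
#' its sign (zero maps to non-anesthesia).
#'
#' @param object a `ppg_svm` model.
#' @param newdata query matrix/data.frame (or single vector).
#' @param ... unused.
#' @return data.frame with `label` and `score` (the decision value).
#' @export
predict.ppg_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv)) {
    stop("query has ", ncol(newdata), " features; model expects ",
         ncol(object$sv))
  }
  Q <- .apply_standardizer(object$std, newdata)
  Kq <- .svm_kernel(Q, object$sv, object$kernel, object$gamma)
  dec <- as.numeric(Kq %*% (object$alpha * object$ysgn)) + object$b
  data.frame(label = factor(.anes_levels[(dec > 0) + 1L],
                            levels = .anes_levels),
             score = dec)
}

#' @export
print.ppg_svm <- function(x, ...) {
  cat(sprintf("<ppg_svm> kernel=%s C=%g n_sv=%d iterations=%d\n",
              x$kernel, x$C, nrow(x$sv), x$n_iter))
  invisible(x)
}
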