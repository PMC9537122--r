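# Ridge regularization for a covariance matrix whose condition number
# exceeds cond_max: add eps * trace(S)/d to the diagonal.
.regularize_cov <- function(S, cond_max = 1e10, eps = 1e-6) {
  d <- ncol(S)
  k <- tryCatch(kappa(S, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k > cond_max) {
    S <- S + diag(eps * sum(diag(S)) / d, d)
  }
  S
}

#' Fit a Gaussian discriminant classifier
#'
#' Class-conditional Gaussians with empirical priors: a pooled covariance
#' for the linear type, per-class covariances for the quadratic type.
#' Near-singular covariances receive a small ridge
#' (`eps * trace(S)/d` on the diagonal).
#'
#' @param X training features (rows = segments).
#' @param y class labels.
#' @param type `"linear"` or `"quadratic"`.
#' @param cost 2x2 classification-cost matrix `C[y, k]` = cost of
#'   deciding `y` when the truth is `k`; the default 0/1 cost makes the
#'   decision rule a posterior argmax.
#' @param standardize standardize features by training mean/sd.
#' @return an object of class `ppg_discriminant`.
#' @export
discriminant_fit <- function(X, y, type = c("linear", "quadratic"),
                             cost = 1 - diag(2), standardize = TRUE) {
  type <- match.arg(type)
  X <- as.matrix(X)
  y <- as_anes_label(y)
  stopifnot(nrow(X) == length(y), all(dim(cost) == c(2, 2)))
  if (length(unique(y)) < 2) stop("both classes must be present")
  std <- .standardizer(X, standardize)
  Xs <- .apply_standardizer(std, X)
  d <- ncol(Xs)
  classes <- levels(y)
  means <- lapply(classes, function(cl) colMeans(Xs[y == cl, , drop = FALSE]))
  priors <- as.numeric(table(y)[classes]) / length(y)
  covs <- if (type == "linear") {
    pooled <- Reduce(`+`, lapply(classes, function(cl) {
      Xc <- Xs[y == cl, , drop = FALSE]
      stats::cov(Xc) * (nrow(Xc) - 1)
    })) / (nrow(Xs) - 2)
    pooled <- .regularize_cov(pooled)
    list(pooled, pooled)
  } else {
    lapply(classes, function(cl) {
      Xc <- Xs[y == cl, , drop = FALSE]
      if (nrow(Xc) < d + 1) {
        warning("class ", cl, " has fewer rows than features + 1; ",
                "covariance regularized")
      }
      .regularize_cov(stats::cov(Xc))
    })
  }
  # precompute cholesky factors for the log-density
  chols <- lapply(covs, chol)
  structure(
    list(type = type, means = means, covs = covs, chols = chols,
         priors = priors, cost = cost, std = std, classes = classes,
         features = colnames(X)),
    class = "ppg_discriminant"
  )
}

.gauss_logdens <- function(x_mat, mean, chol_S) {
  dev <- sweep(x_mat, 2, mean, "-")
  z <- dev %*% solve(chol_S)  # rows whitened: backsolve against R
  -0.5 * rowSums(z^2) - sum(log(diag(chol_S))) -
    0.5 * ncol(x_mat) * log(2 * pi)
}

#' Predict with a discriminant model
#'
#' Posteriors follow from the Gaussian class-conditionals and priors; the
#' decision minimizes the expected classification cost
#' `sum_k P(k | x) C(y | k)`, which with the default 0/1 cost is the
#' posterior argmax.  Exact expected-cost ties go to the first
#' (non-anesthesia) class.
#'
#' @param object a `ppg_discriminant` model.
#' @param newdata query matrix/data.frame (or single vector).
#' @param ... unused.
#' @return data.frame with `label` and `score` (posterior probability of
#'   the anesthesia class).
#' @export
predict.ppg_discriminant <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (!all(is.finite(newdata))) stop("non-finite feature values")
  Q <- .apply_standardizer(object$std, newdata)
  logp <- vapply(1:2, function(kk) {
    .gauss_logdens(Q, object$means[[kk]], object$chols[[kk]]) +
      log(object$priors[kk])
  }, numeric(nrow(Q)))
  logp <- matrix(logp, ncol = 2)
  m <- apply(logp, 1, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  # expected cost of deciding y = 1, 2 (rows of the cost matrix)
  expected <- post %*% t(object$cost)
  lab <- ifelse(expected[, 2] < expected[, 1], 2L, 1L)
  data.frame(label = factor(object$classes[lab], levels = object$classes),
             score = post[, 2],
             posterior_non_anesthesia = post[, 1],
             posterior_anesthesia = post[, 2])
}

#' @export
print.ppg_discriminant <- function(x, ...) {
  cat(sprintf("<ppg_discriminant> type=%s d=%d priors=%.2f/%.2f\n",
              x$type, length(x$means[[1]]), x$priors[1], x$priors[2]))
  invisible(x)
}
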