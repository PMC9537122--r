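# Shared feature standardization: train-set mean/sd, applied to queries.
.standardizer <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  if (!standardize) {
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.apply_standardizer <- function(std, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Minkowski distance
#'
#' `(sum_j |x_j - y_j|^p)^(1/p)`; p = 1 is city-block, p = 2 Euclidean,
#' and the p -> infinity limit is the Chebychev (max) distance.
#'
#' @param x,y numeric vectors of equal length.
#' @param p order, >= 1.
#' @return non-negative distance.
#' @export
minkowski_distance <- function(x, y, p = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (p < 1) stop("p must be at least 1")
  sum(abs(x - y)^p)^(1 / p)
}

# Distance from every training row to every query row; rows of the result
# index queries, columns index training points.
.knn_distances <- function(train, query, metric, p, inv_chol = NULL) {
  qn <- nrow(query)
  switch(metric,
    euclidean = .pair_minkowski(train, query, 2),
    minkowski = .pair_minkowski(train, query, p),
    cityblock = .pair_minkowski(train, query, 1),
    chebychev = t(apply(query, 1, function(q)
      apply(abs(sweep(train, 2, q, "-")), 1, max))),
    mahalanobis = {
      # whiten with the training covariance, then Euclidean
      .pair_minkowski(train %*% inv_chol, query %*% inv_chol, 2)
    },
    cosine = {
      nt <- sqrt(rowSums(train^2)); nq <- sqrt(rowSums(query^2))
      nt[nt == 0] <- 1; nq[nq == 0] <- 1
      1 - (query %*% t(train)) / outer(nq, nt)
    },
    correlation = {
      tc <- train - rowMeans(train); qc <- query - rowMeans(query)
      nt <- sqrt(rowSums(tc^2)); nq <- sqrt(rowSums(qc^2))
      nt[nt == 0] <- 1; nq[nq == 0] <- 1
      1 - (qc %*% t(tc)) / outer(nq, nt)
    },
    stop("unknown metric: ", metric)
  )
}

.pair_minkowski <- function(train, query, p) {
  if (p == 2) {
    d2 <- outer(rowSums(query^2), rowSums(train^2), "+") -
      2 * query %*% t(train)
    sqrt(pmax(d2, 0))
  } else {
    t(apply(query, 1, function(q)
      rowSums(abs(sweep(train, 2, q, "-"))^p)^(1 / p)))
  }
}

#' Fit a k-nearest-neighbor classifier
#'
#' Stores the (optionally standardized) training matrix and labels; all
#' work happens at prediction time.
#'
#' @param X numeric matrix or data.frame of training features (rows =
#'   segments).
#' @param y class labels (see [as_anes_label()]).
#' @param k number of neighbors (1 <= k <= nrow(X)).
#' @param metric one of `"euclidean"`, `"minkowski"`, `"cityblock"`,
#'   `"chebychev"`, `"mahalanobis"`, `"cosine"`, `"correlation"`.
#' @param p Minkowski order (used when `metric = "minkowski"`).
#' @param weighting `"uniform"` (majority vote) or `"inverse"`
#'   (inverse-distance-weighted vote).
#' @param standardize standardize features by training mean/sd.
#' @return an object of class `ppg_knn`.
#' @export
knn_fit <- function(X, y, k = 3,
                    metric = c("euclidean", "minkowski", "cityblock",
                               "chebychev", "mahalanobis", "cosine",
                               "correlation"),
                    p = 2, weighting = c("uniform", "inverse"),
                    standardize = TRUE) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  X <- as.matrix(X)
  y <- as_anes_label(y)
  stopifnot(nrow(X) == length(y), k >= 1, k <= nrow(X), p >= 1)
  std <- .standardizer(X, standardize)
  Xs <- .apply_standardizer(std, X)
  inv_chol <- NULL
  if (metric == "mahalanobis") {
    S <- stats::cov(Xs)
    S <- .regularize_cov(S)
    inv_chol <- solve(chol(S))
  }
  structure(
    list(X = Xs, y = y, k = as.integer(k), metric = metric, p = p,
         weighting = weighting, std = std, inv_chol = inv_chol,
         features = colnames(X)),
    class = "ppg_knn"
  )
}

#' Predict with a KNN model
#'
#' Uniform weighting takes the majority label of the k nearest training
#' points; a tied vote goes to the single nearest neighbor's class.
#' Inverse weighting maximizes the summed `1/d` over neighbors; an
#' exact-match neighbor (`d = 0`) wins outright (the `1/d` limit), with a
#' majority vote among exact matches if there are several.  Distance ties
#' are broken by training-row order.  The score is the positive-class
#' share of the vote weight, usable as a ROC statistic.
#'
#' @param object a `ppg_knn` model.
#' @param newdata query matrix/data.frame (or a single vector).
#' @param ... unused.
#' @return data.frame with `label` (factor) and `score` (positive-class
#'   weight fraction).
#' @export
predict.ppg_knn <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) {
    stop("query has ", ncol(newdata), " features; model expects ",
         ncol(object$X))
  }
  Q <- .apply_standardizer(object$std, newdata)
  D <- .knn_distances(object$X, Q, object$metric, object$p, object$inv_chol)
  D <- matrix(D, nrow = nrow(Q))
  y01 <- as.integer(object$y) - 1L
  k <- object$k
  res <- vapply(seq_len(nrow(Q)), function(i) {
    d <- D[i, ]
    ord <- order(d)[seq_len(k)]
    dn <- d[ord]; yn <- y01[ord]
    if (object$weighting == "uniform") {
      pos <- sum(yn); neg <- k - pos
      score <- pos / k
      lab <- if (pos > neg) 1L else if (pos < neg) 0L else yn[1]
    } else {
      if (any(dn == 0)) {
        exact <- yn[dn == 0]
        pos <- sum(exact); neg <- length(exact) - pos
        score <- pos / length(exact)
        lab <- if (pos > neg) 1L else if (pos < neg) 0L else yn[1]
      } else {
        w <- 1 / dn
        pos <- sum(w[yn == 1]); neg <- sum(w[yn == 0])
        score <- pos / (pos + neg)
        lab <- if (pos > neg) 1L else if (pos < neg) 0L else yn[1]
      }
    }
    c(lab, score)
  }, numeric(2))
  data.frame(label = factor(.anes_levels[res[1, ] + 1L],
                            levels = .anes_levels),
             score = res[2, ])
}

#' @export
print.ppg_knn <- function(x, ...) {
  cat(sprintf("<ppg_knn> k=%d metric=%s%s weighting=%s n_train=%d d=%d\n",
              x$k, x$metric,
              if (x$metric == "minkowski") sprintf("(p=%g)", x$p) else "",
              x$weighting, nrow(x$X), ncol(x$X)))
  invisible(x)
}
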