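# Brute-force KNN used as the independent oracle: plain loops, full sort,
# and the same documented tie rules as the package implementation.
brute_knn <- function(X, y01, query, k, metric, p = 2, weighting,
                      inv_chol = NULL) {
  dist_one <- function(a, b) {
    switch(metric,
      euclidean = sqrt(sum((a - b)^2)),
      cityblock = sum(abs(a - b)),
      chebychev = max(abs(a - b)),
      minkowski = sum(abs(a - b)^p)^(1 / p),
      mahalanobis = sqrt(sum(((a - b) %*% inv_chol)^2)),
      cosine = 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))),
      correlation = 1 - stats::cor(a, b)
    )
  }
  d <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) d[i] <- dist_one(X[i, ], query)
  ord <- order(d)
  nn <- ord[seq_len(k)]
  dn <- d[nn]; yn <- y01[nn]
  if (weighting == "uniform") {
    pos <- sum(yn)
    if (pos * 2 == k) yn[1] else as.integer(pos * 2 > k)
  } else if (any(dn == 0)) {
    exact <- yn[dn == 0]
    pos <- sum(exact)
    if (pos * 2 == length(exact)) yn[1] else
      as.integer(pos * 2 > length(exact))
  } else {
    w <- 1 / dn
    pos <- sum(w[yn == 1]); neg <- sum(w[yn == 0])
    if (pos == neg) yn[1] else as.integer(pos > neg)
  }
}

test_that("Minkowski distance matches closed-form cases", {
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 2), 5)
  expect_equal(minkowski_distance(c(1, 1), c(4, 5), 1), 7)
  # large p approaches the Chebychev (max) limit
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 50), 4,
               tolerance = 1e-2)
  expect_error(minkowski_distance(1:2, 1:2, 0.5), "at least 1")
  expect_error(minkowski_distance(1:2, 1:3), "equal length")
})

test_that("KNN predictions match the brute-force oracle", {
  withr::with_seed(101, {
    X <- matrix(rnorm(60 * 3), ncol = 3)
    y <- rbinom(60, 1, 0.5)
    Q <- matrix(rnorm(20 * 3), ncol = 3)
    for (metric in c("euclidean", "cityblock", "chebychev", "minkowski",
                     "mahalanobis", "cosine", "correlation")) {
      for (k in c(1, 3, 6)) {
        for (w in c("uniform", "inverse")) {
          m <- knn_fit(X, y, k = k, metric = metric, p = 3, weighting = w,
                       standardize = FALSE)
          pred <- predict(m, Q)
          oracle <- vapply(seq_len(nrow(Q)), function(i)
            brute_knn(X, y, Q[i, ], k, metric, p = 3, w,
                      inv_chol = m$inv_chol), integer(1))
          expect_equal(as.integer(pred$label) - 1L, oracle)
        }
      }
    }
  })
})

test_that("KNN honors its documented tie and exact-match rules", {
  # query equal to a training point with k = 1 returns that point's label
  X <- rbind(c(0, 0), c(5, 5), c(6, 6))
  y <- c(1, 0, 0)
  for (metric in c("euclidean", "cityblock", "chebychev")) {
    m <- knn_fit(X, y, k = 1, metric = metric, standardize = FALSE)
    expect_equal(as.character(predict(m, c(0, 0))$label), "anesthesia")
  }
  # inverse weighting: an exact match wins outright over closer mass
  m <- knn_fit(rbind(c(0, 0), c(0.1, 0), c(0.11, 0)), c(1, 0, 0),
               k = 3, weighting = "inverse", standardize = FALSE)
  expect_equal(as.character(predict(m, c(0, 0))$label), "anesthesia")
  expect_equal(predict(m, c(0, 0))$score, 1)
  # uniform even-k tie falls to the nearest neighbor's class
  m2 <- knn_fit(rbind(c(0, 1), c(0, 2)), c(1, 0), k = 2,
                standardize = FALSE)
  expect_equal(as.character(predict(m2, c(0, 0.9))$label), "anesthesia")
})

test_that("k = 1 KNN has zero training error on distinct points", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40 * 2), ncol = 2)
    y <- rbinom(40, 1, 0.5)
    m <- knn_fit(X, y, k = 1)
    expect_equal(mean(predict(m, X)$label != as_anes_label(y)), 0)
  })
})

test_that("discriminant analysis recovers the closed-form 1-D boundary", {
  # mirrored samples: equal variances and priors put the linear boundary
  # at the midpoint of the class means
  x0 <- c(-3, -2, -1, -2.5, -1.5)
  x1 <- -x0 + 1          # mirrored around 0.5
  X <- matrix(c(x0, x1), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  m <- discriminant_fit(X, y, type = "linear", standardize = FALSE)
  dec <- function(v) {
    p <- predict(m, matrix(v, ncol = 1))
    p$posterior_anesthesia - 0.5
  }
  boundary <- stats::uniroot(dec, c(-3, 4), tol = 1e-9)$root
  expect_equal(boundary, 0.5, tolerance = 1e-6)
  # query at each class mean classifies to that class
  expect_equal(as.character(predict(m, mean(x0))$label), "non_anesthesia")
  expect_equal(as.character(predict(m, mean(x1))$label), "anesthesia")
})

test_that("discriminant posteriors normalize and drive the cost rule", {
  withr::with_seed(19, {
    X <- rbind(matrix(rnorm(30, 0), ncol = 2),
               matrix(rnorm(30, 1.5), ncol = 2))
    y <- rep(c(0, 1), each = 15)
    for (type in c("linear", "quadratic")) {
      m <- discriminant_fit(X, y, type = type)
      p <- predict(m, matrix(rnorm(40), ncol = 2))
      expect_equal(p$posterior_anesthesia + p$posterior_non_anesthesia,
                   rep(1, 20), tolerance = 1e-12)
      # with 0/1 costs the decision is the posterior argmax
      expect_equal(as.integer(p$label) - 1L,
                   as.integer(p$posterior_anesthesia > 0.5))
    }
    # an asymmetric cost flips a decision at posterior 0.2: deciding
    # non-anesthesia costs 10 * P(anesthesia) = 2 > deciding anesthesia
    # at 0.8, so the anesthesia call wins
    cost <- matrix(c(0, 1, 10, 0), nrow = 2)  # C[y, k], C[1,2] = 10
    m10 <- discriminant_fit(X, y, type = "linear", cost = cost)
    p0 <- predict(discriminant_fit(X, y, type = "linear"), X)
    pc <- predict(m10, X)
    flip <- p0$posterior_anesthesia > 0.1 & p0$posterior_anesthesia < 0.5
    expect_true(all(pc$label[flip] == "anesthesia"))
  })
})

test_that("the two-point SVM matches the maximal-margin closed form", {
  X <- rbind(c(0, 0), c(2, 0))
  y <- c(0, 1)
  m <- svm_fit(X, y, C = 1e4, kernel = "linear", standardize = FALSE)
  expect_equal(m$beta, c(1, 0), tolerance = 1e-3)
  expect_equal(m$b_raw, -1, tolerance = 1e-3)
  # support vectors satisfy y f(x) = 1 within the gap tolerance
  f <- predict(m, X)$score
  expect_lt(max(abs(c(-1, 1) * f - 1)), 1e-3 + 1e-6)
  # a point on the hyperplane scores ~0
  expect_equal(predict(m, c(1, 0))$score, 0, tolerance = 1e-3)
})

test_that("SVM respects label-flip and translation symmetries", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(20, 0), ncol = 2),
               matrix(rnorm(20, 3), ncol = 2))
    y <- rep(c(0, 1), each = 10)
    m1 <- svm_fit(X, y, C = 10, kernel = "linear", standardize = FALSE)
    m2 <- svm_fit(X, 1 - y, C = 10, kernel = "linear",
                  standardize = FALSE)
    expect_equal(m1$beta, -m2$beta, tolerance = 1e-3)
    expect_equal(m1$b_raw, -m2$b_raw, tolerance = 1e-3)
    # translating all data leaves linear-kernel predictions unchanged
    shift <- c(5, -3)
    m3 <- svm_fit(sweep(X, 2, shift, "+"), y, C = 10, kernel = "linear",
                  standardize = FALSE)
    Q <- matrix(rnorm(20), ncol = 2)
    expect_equal(predict(m1, Q)$score,
                 predict(m3, sweep(Q, 2, shift, "+"))$score,
                 tolerance = 1e-3)
  })
})

test_that("the SMO dual agrees with an independent SVM solver", {
  skip_if_not_installed("e1071")
  withr::with_seed(77, {
    X <- rbind(matrix(rnorm(24, 0), ncol = 2),
               matrix(rnorm(24, 2.5), ncol = 2))
    y <- rep(c(0, 1), each = 12)
    for (C in c(0.5, 5)) {
      m <- svm_fit(X, y, C = C, kernel = "linear", standardize = FALSE)
      ref <- e1071::svm(X, factor(y), kernel = "linear", cost = C,
                        scale = FALSE)
      beta_ref <- colSums(ref$coefs[, 1] * ref$SV)
      # e1071 codes the first factor level +1; align signs via the label
      sgn <- if (ref$labels[1] == 2) 1 else -1
      expect_equal(m$beta, unname(sgn * beta_ref), tolerance = 5e-3)
      expect_equal(m$b_raw, sgn * -ref$rho, tolerance = 5e-3)
    }
  })
})

test_that("increasing C never increases margin violations when separable", {
  withr::with_seed(41, {
    X <- rbind(matrix(rnorm(20, 0, 0.5), ncol = 2),
               matrix(rnorm(20, 3, 0.5), ncol = 2))
    y <- rep(c(0, 1), each = 10)
    ysgn <- ifelse(y == 1, 1, -1)
    viol <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
      m <- svm_fit(X, y, C = C, kernel = "linear", standardize = FALSE)
      sum(ysgn * predict(m, X)$score < 1 - 1e-6)
    }, numeric(1))
    expect_true(all(diff(viol) <= 0))
  })
})

test_that("models serialize to JSON and back without changing predictions", {
  withr::with_seed(13, {
    X <- rbind(matrix(rnorm(30, 0), ncol = 2),
               matrix(rnorm(30, 2), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- rep(c(0, 1), each = 15)
    Q <- matrix(rnorm(24), ncol = 2)
    models <- list(
      knn_fit(X, y, k = 3, weighting = "inverse"),
      knn_fit(X, y, k = 5, metric = "mahalanobis"),
      discriminant_fit(X, y, type = "quadratic"),
      svm_fit(X, y, C = 2, kernel = "gaussian")
    )
    for (m in models) {
      path <- withr::local_tempfile(fileext = ".json")
      model_to_json(m, path)
      back <- model_from_json(path)
      expect_equal(predict(back, Q), predict(m, Q), tolerance = 1e-12)
    }
  })
})

test_that("linear discriminant posteriors agree with an independent fit", {
  skip_if_not_installed("MASS")
  withr::with_seed(29, {
    X <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(40, 1.2), ncol = 2))
    y <- rep(c(0, 1), each = 20)
    m <- discriminant_fit(X, y, type = "linear", standardize = FALSE)
    ref <- MASS::lda(X, grouping = factor(y))
    Q <- matrix(rnorm(30), ncol = 2)
    ours <- predict(m, Q)$posterior_anesthesia
    theirs <- predict(ref, Q)$posterior[, "1"]
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  })
})
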