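#' Hyperparameter search spaces
#'
#' Default search domains for the three classifier families: KNN searches
#' k in 1-30 over the metric set and both weightings; the discriminant
#' searches its type; the SVM searches log10(C) in [-3, 3] over the
#' kernel set.
#'
#' @param family `"knn"`, `"discriminant"`, or `"svm"`.
#' @return a named list of parameter domains (class `ppg_search_space`):
#'   each entry is `list(type = "int"|"num"|"cat", ...)` with
#'   `lower`/`upper` bounds or `values`, plus an optional `transform`.
#' @export
search_space <- function(family = c("knn", "discriminant", "svm")) {
  family <- match.arg(family)
  sp <- switch(family,
    knn = list(
      k = list(type = "int", lower = 1, upper = 30),
      metric = list(type = "cat",
                    values = c("euclidean", "cityblock", "chebychev",
                               "minkowski", "mahalanobis", "cosine",
                               "correlation")),
      weighting = list(type = "cat", values = c("uniform", "inverse"))
    ),
    discriminant = list(
      type = list(type = "cat", values = c("linear", "quadratic"))
    ),
    svm = list(
      C = list(type = "num", lower = -3, upper = 3,
               transform = function(v) 10^v),
      kernel = list(type = "cat",
                    values = c("linear", "gaussian", "cubic"))
    )
  )
  structure(sp, class = "ppg_search_space", family = family)
}

# Draw one random configuration from a space (uses the current RNG).
.space_sample <- function(space) {
  lapply(space, function(p) {
    switch(p$type,
      int = sample(seq(p$lower, p$upper), 1),
      num = runif(1, p$lower, p$upper),
      cat = sample(p$values, 1)
    )
  })
}

# Encode a configuration as a numeric vector in [0, 1]^m for the
# surrogate model (one-hot for categoricals).
.space_encode <- function(space, config) {
  unlist(Map(function(p, v) {
    switch(p$type,
      int = (v - p$lower) / max(1, p$upper - p$lower),
      num = (v - p$lower) / (p$upper - p$lower),
      cat = as.numeric(p$values == v)
    )
  }, space, config[names(space)]))
}

# Apply any transforms to obtain the hyperparameters actually passed to
# the classifier.
.space_materialize <- function(space, config) {
  out <- Map(function(p, v) {
    if (!is.null(p$transform)) p$transform(v) else v
  }, space, config[names(space)])
  out
}

# Minimal Gaussian-process regression with a squared-exponential kernel
# for the expected-improvement surrogate.
.gp_fit <- function(Xe, y, lengthscale = 0.4) {
  n <- nrow(Xe)
  sig2 <- max(var(y), 1e-8)
  d2 <- as.matrix(dist(Xe))^2
  K <- sig2 * exp(-d2 / (2 * lengthscale^2))
  Kn <- K + diag(1e-6 * sig2 + 1e-8, n)
  L <- chol(Kn)
  alpha <- backsolve(L, forwardsolve(t(L), y - mean(y)))
  list(Xe = Xe, L = L, alpha = alpha, mean = mean(y), sig2 = sig2,
       lengthscale = lengthscale)
}

.gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$Xe^2), "+") -
    2 * Xnew %*% t(gp$Xe)
  Ks <- gp$sig2 * exp(-pmax(d2, 0) / (2 * gp$lengthscale^2))
  mu <- gp$mean + Ks %*% gp$alpha
  v <- forwardsolve(t(gp$L), t(Ks))
  var <- pmax(gp$sig2 - colSums(v^2), 1e-12)
  list(mean = as.numeric(mu), sd = sqrt(var))
}

# Expected improvement (minimization) at predicted mean/sd given the
# incumbent best value.
.expected_improvement <- function(mu, sdv, best) {
  z <- (best - mu) / sdv
  (best - mu) * stats::pnorm(z) + sdv * dnorm(z)
}

#' Sequential model-based hyperparameter optimization
#'
#' Minimizes the subject-grouped cross-validation error over a search
#' space: 5 seeded random warm-up evaluations followed by
#' expected-improvement proposals from a Gaussian-process surrogate over
#' a random candidate pool (`method = "random"` falls back to pure
#' random search).  The trace of every evaluation and the running
#' incumbent is returned.
#'
#' @param table feature table.
#' @param features feature columns.
#' @param family classifier family.
#' @param space a [search_space()] (defaults to the family's).
#' @param iterations total evaluations (default 30).
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @param method `"gp"` (surrogate) or `"random"`.
#' @param objective optional custom objective `function(params) -> error`
#'   replacing the cross-validation score (used for testing and for mock
#'   tuning curves).
#' @param n_warmup random evaluations before the surrogate starts.
#' @param n_candidates candidate-pool size per surrogate iteration.
#' @return list with `best_params` (materialized hyperparameters),
#'   `best_error`, and `trace` (data.frame with one row per evaluation:
#'   the raw configuration, its error, and the incumbent error).
#' @export
optimize_hyperparams <- function(table = NULL, features = NULL,
                                 family = c("knn", "discriminant", "svm"),
                                 space = NULL, iterations = 30, folds = 10,
                                 seed = 1L, method = c("gp", "random"),
                                 objective = NULL, n_warmup = 5,
                                 n_candidates = 100) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (iterations < 1) stop("iteration budget must be at least 1")
  if (is.null(space)) space <- search_space(family)
  if (is.null(objective)) {
    stopifnot(!is.null(table), !is.null(features))
    objective <- function(config) {
      params <- .space_materialize(space, config)
      grouped_kfold_cv(table, features, family, params,
                       folds = folds, seed = seed)$error
    }
  }
  # enumerate the whole space when it is small and purely categorical
  withr::with_seed(derive_seed(seed, paste0("opt/", family)), {
    evaluated <- list(); errors <- numeric(0)
    key_of <- function(cfg) paste(unlist(cfg), collapse = "|")
    seen <- character(0)
    propose_random <- function() {
      for (try in 1:50) {
        cfg <- .space_sample(space)
        if (!key_of(cfg) %in% seen) return(cfg)
      }
      cfg
    }
    for (it in seq_len(iterations)) {
      cfg <- NULL
      if (method == "gp" && it > n_warmup && length(errors) >= 3) {
        Xe <- do.call(rbind, lapply(evaluated, .space_encode,
                                    space = space))
        gp <- tryCatch(.gp_fit(Xe, errors), error = function(e) NULL)
        if (!is.null(gp)) {
          pool <- replicate(n_candidates, .space_sample(space),
                            simplify = FALSE)
          keep <- !vapply(pool, function(c) key_of(c) %in% seen,
                          logical(1))
          pool <- pool[keep]
          if (length(pool)) {
            Pe <- do.call(rbind, lapply(pool, .space_encode,
                                        space = space))
            pr <- .gp_predict(gp, Pe)
            ei <- .expected_improvement(pr$mean, pr$sd, min(errors))
            cfg <- pool[[which.max(ei)]]
          }
        }
      }
      if (is.null(cfg)) cfg <- propose_random()
      seen <- c(seen, key_of(cfg))
      err <- objective(cfg)
      evaluated[[it]] <- cfg
      errors[it] <- err
    }
    best <- which.min(errors)
    trace <- do.call(rbind, lapply(seq_along(evaluated), function(i) {
      row <- as.data.frame(evaluated[[i]], stringsAsFactors = FALSE)
      row$error <- errors[i]
      row$incumbent <- min(errors[seq_len(i)])
      row$iteration <- i
      row
    }))
    list(best_params = .space_materialize(space, evaluated[[best]]),
         best_config = evaluated[[best]],
         best_error = errors[best], trace = trace)
  })
}
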