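#' Classifier presets
#'
#' Named hyperparameter presets for the three families.  `knn` is the
#' tuned headline configuration (k = 3, Euclidean, inverse-distance
#' weighting); `knn_minkowski6` is the alternative described with the
#' Minkowski metric and 6 neighbors; `discriminant` is the plain linear
#' discriminant (with `discriminant_quadratic` as the tuned alternative);
#' the SVM appears as a linear-kernel preset plus the two reported tuned
#' variants (cubic kernel with C = 0.32, Gaussian kernel with C = 7.59),
#' which are both kept because the two reported optima disagree.
#'
#' @return named list; each element has `family` and `params`.
#' @export
classifier_presets <- function() {
  list(
    knn = list(family = "knn",
               params = list(k = 3, metric = "euclidean",
                             weighting = "inverse")),
    knn_minkowski6 = list(family = "knn",
                          params = list(k = 6, metric = "minkowski", p = 2,
                                        weighting = "uniform")),
    discriminant = list(family = "discriminant",
                        params = list(type = "linear")),
    discriminant_quadratic = list(family = "discriminant",
                                  params = list(type = "quadratic")),
    svm_linear = list(family = "svm",
                      params = list(C = 1, kernel = "linear")),
    svm_cubic = list(family = "svm",
                     params = list(C = 0.32, kernel = "cubic")),
    svm_gaussian = list(family = "svm",
                        params = list(C = 7.59, kernel = "gaussian"))
  )
}

#' Serialize a fitted classifier to JSON
#'
#' Writes hyperparameters and model arrays to a documented JSON schema
#' (`model_type`, `features`, `standardizer`, plus family-specific
#' fields), full double precision.
#'
#' @param model a `ppg_knn`, `ppg_discriminant`, or `ppg_svm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  obj <- if (inherits(model, "ppg_knn")) {
    list(model_type = "knn", k = model$k, metric = model$metric,
         p = model$p, weighting = model$weighting,
         features = model$features, standardizer = model$std,
         X = model$X, y = as.character(model$y),
         inv_chol = model$inv_chol)
  } else if (inherits(model, "ppg_discriminant")) {
    list(model_type = "discriminant", type = model$type,
         features = model$features, standardizer = model$std,
         means = model$means, covs = model$covs, priors = model$priors,
         cost = model$cost, classes = model$classes)
  } else if (inherits(model, "ppg_svm")) {
    list(model_type = "svm", kernel = model$kernel, gamma = model$gamma,
         C = model$C, tol = model$tol, features = model$features,
         standardizer = model$std, sv = model$sv, alpha = model$alpha,
         ysgn = model$ysgn, b = model$b, beta = model$beta,
         b_raw = model$b_raw)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Restore a classifier from JSON
#'
#' @param path file written by [model_to_json()].
#' @return the fitted classifier object.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- list(center = as.numeric(obj$standardizer$center),
              scale = as.numeric(obj$standardizer$scale))
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    storage.mode(m) <- "double"
    m
  }
  switch(obj$model_type,
    knn = structure(
      list(X = as_mat(obj$X), y = as_anes_label(obj$y), k = obj$k,
           metric = obj$metric, p = obj$p, weighting = obj$weighting,
           std = std, inv_chol = as_mat(obj$inv_chol),
           features = obj$features),
      class = "ppg_knn"),
    discriminant = {
      # a list of equal-dimension matrices may come back as a 3-d array
      split_first <- function(x, as_matrix) {
        if (is.array(x) && length(dim(x)) == 3) {
          lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
        } else if (is.matrix(x) && !as_matrix) {
          lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
        } else if (as_matrix) {
          lapply(x, as_mat)
        } else {
          lapply(x, as.numeric)
        }
      }
      covs <- split_first(obj$covs, as_matrix = TRUE)
      obj$means <- split_first(obj$means, as_matrix = FALSE)
      structure(
        list(type = obj$type, means = obj$means,
             covs = covs, chols = lapply(covs, chol),
             priors = as.numeric(obj$priors), cost = as_mat(obj$cost),
             std = std, classes = obj$classes, features = obj$features),
        class = "ppg_discriminant")
    },
    svm = structure(
      list(kernel = obj$kernel, gamma = obj$gamma, C = obj$C,
           tol = obj$tol, sv = as_mat(obj$sv),
           alpha = as.numeric(obj$alpha), ysgn = as.numeric(obj$ysgn),
           b = obj$b, beta = if (is.null(obj$beta)) NULL else
             as.numeric(obj$beta),
           b_raw = obj$b_raw, std = std, n_iter = NA_integer_,
           features = obj$features),
      class = "ppg_svm"),
    stop("unknown model_type in ", path)
  )
}
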