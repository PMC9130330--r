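#' Classifier adapters
#'
#' The cross-validation harness talks to classifiers through a minimal
#' adapter contract: a list with a `name`, a `fit(table)` function
#' returning an opaque model, and a `predict(model, table)` function
#' returning a vector of class labels for the rows of `table`. One
#' reference classifier — a naive Bayes with Laplace-smoothed tables for
#' categorical features and per-class Gaussians for continuous ones —
#' ships in-package so the harness has no heavyweight dependency.
#' Logistic regression attaches through `stats::glm`; random forest and
#' SVM adapters attach to their ecosystem packages when installed.
#'
#' @param laplace Additive smoothing count for categorical likelihoods.
#' @return An adapter list with `name`, `fit`, `predict`.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classifier_nb <- function(laplace = 1) {
  fit <- function(table) {
    cn <- attr(table, "class_name")
    schema <- attr(table, "schema")
    y <- table[[cn]]
    classes <- levels(y)
    prior <- table(y) / length(y)
    feats <- lapply(schema, function(fs) {
      v <- table[[fs$name]]
      if (fs$kind == "categorical") {
        per_class <- lapply(classes, function(cl) {
          cnt <- table(factor(v[y == cl], levels = fs$levels)) + laplace
          cnt / sum(cnt)
        })
        list(kind = "categorical", levels = fs$levels,
             prob = stats::setNames(per_class, classes))
      } else {
        per_class <- lapply(classes, function(cl) {
          x <- v[y == cl]
          s <- if (length(x) >= 2) stats::sd(x) else 0
          list(mu = mean(x), sd = max(s, 1e-6))
        })
        list(kind = "continuous", par = stats::setNames(per_class, classes))
      }
    })
    names(feats) <- schema_names(schema)
    list(classes = classes, prior = prior, feats = feats)
  }
  predict <- function(model, table) {
    n <- nrow(table)
    ll <- sapply(model$classes, function(cl) {
      acc <- rep(log(as.numeric(model$prior[[cl]])), n)
      for (fn in names(model$feats)) {
        f <- model$feats[[fn]]
        if (f$kind == "categorical") {
          p <- as.numeric(f$prob[[cl]][as.character(table[[fn]])])
          acc <- acc + log(p)
        } else {
          par <- f$par[[cl]]
          acc <- acc + stats::dnorm(table[[fn]], par$mu, par$sd, log = TRUE)
        }
      }
      acc
    })
    ll <- matrix(ll, nrow = n)
    model$classes[max.col(ll, ties.method = "first")]
  }
  list(name = "nb", fit = fit, predict = predict)
}

#' @rdname classifiers
#' @export
classifier_logreg <- function() {
  fit <- function(table) {
    cn <- attr(table, "class_name")
    df <- as.data.frame(table)
    df$.y <- as.integer(as.character(df[[cn]]) == "+")
    df[[cn]] <- NULL
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial))
  }
  predict <- function(model, table) {
    df <- as.data.frame(table)
    df[[attr(table, "class_name")]] <- NULL
    p <- suppressWarnings(
      stats::predict(model, newdata = df, type = "response"))
    ifelse(p >= 0.5, "+", "-")
  }
  list(name = "logreg", fit = fit, predict = predict)
}

#' @rdname classifiers
#' @param ntree Number of trees for the random forest adapter.
#' @export
classifier_rf <- function(ntree = 500) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("package 'randomForest' is required for this adapter")
  fit <- function(table) {
    cn <- attr(table, "class_name")
    df <- as.data.frame(table)
    randomForest::randomForest(stats::reformulate(".", response = cn),
                               data = df, ntree = ntree)
  }
  predict <- function(model, table) {
    as.character(stats::predict(model, newdata = as.data.frame(table)))
  }
  list(name = "rf", fit = fit, predict = predict)
}

#' @rdname classifiers
#' @export
classifier_svm <- function() {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("package 'e1071' is required for this adapter")
  fit <- function(table) {
    cn <- attr(table, "class_name")
    df <- as.data.frame(table)
    e1071::svm(stats::reformulate(".", response = cn), data = df,
               kernel = "radial")
  }
  predict <- function(model, table) {
    as.character(stats::predict(model, newdata = as.data.frame(table)))
  }
  list(name = "svm", fit = fit, predict = predict)
}
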