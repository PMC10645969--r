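#' Default hyperparameter tuning grid
#'
#' A deliberately small grid for desk-scale runs of the random-forest family:
#' 200 trees, maximum depth in \{4, 8, unlimited\}, minimum node size in
#' \{1, 5\}. Each row is one hyperparameter setting passed to
#' [fit_classifier()].
#'
#' @param family `"rf"` (bagged decision trees) or `"logistic"`
#'   (elastic-net regularized logistic regression).
#' @return Data frame, one row per hyperparameter combination.
#' @export
default_tuning_grid <- function(family = c("rf", "logistic")) {
  family <- match.arg(family)
  if (family == "rf") {
    expand.grid(num_trees = 200, max_depth = c(4, 8, 0), min_node = c(1, 5))
  } else {
    expand.grid(alpha = c(0, 0.5), lambda = c(0.01, 0.1, 1))
  }
}

labels_as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels) || is.character(labels)) {
    u <- unique(as.character(labels))
    if (!all(u %in% c("case", "control"))) {
      stop("labels must be logical or use the values 'case'/'control'")
    }
    return(as.character(labels) == "case")
  }
  stop("labels must be logical or a case/control factor")
}

#' Fit a binary spectral classifier
#'
#' Fits the configured estimator family on a feature matrix (one row per
#' spectrum). Scores returned by [predict_scores()] are probabilities of the
#' case class. The default family is a random forest of probability trees
#' (robust to the strong collinearity of spectral features and yielding
#' native impurity importances); a regularized logistic alternative is
#' provided behind the same interface.
#'
#' @param features Numeric matrix, rows = spectra, columns = features.
#' @param labels Logical case indicator (or `"case"`/`"control"` vector),
#'   one per row; both classes must be present.
#' @param hp One row of a tuning grid (list or 1-row data frame); see
#'   [default_tuning_grid()]. Missing entries take that grid's first row.
#' @param family `"rf"` or `"logistic"`.
#' @param seed Integer seed; fits are bit-reproducible under a fixed seed.
#' @return Object of class `spec_model`.
#' @export
fit_classifier <- function(features, labels, hp = NULL,
                           family = c("rf", "logistic"), seed = 1L) {
  family <- match.arg(family)
  is_case <- labels_as_case(labels)
  if (nrow(features) != length(is_case)) {
    stop("features rows and labels length differ")
  }
  if (length(unique(is_case)) < 2) {
    stop("training set must contain both classes")
  }
  defaults <- as.list(default_tuning_grid(family)[1, , drop = FALSE])
  hp <- utils::modifyList(defaults, as.list(hp %||% list()))
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("wn", seq_len(ncol(features)))
  }
  y <- factor(ifelse(is_case, "case", "control"),
              levels = c("control", "case"))
  if (family == "rf") {
    df <- as.data.frame(features)
    fit <- ranger::ranger(
      x = df, y = y, probability = TRUE,
      num.trees = hp$num_trees, max.depth = hp$max_depth,
      min.node.size = hp$min_node, importance = "impurity",
      seed = as.integer(seed), num.threads = 1, verbose = FALSE)
  } else {
    fit <- glmnet::glmnet(features, y, family = "binomial",
                          alpha = hp$alpha, lambda = hp$lambda,
                          standardize = TRUE)
  }
  structure(list(family = family, fit = fit, hp = hp,
                 feature_names = colnames(features),
                 n_features = ncol(features)),
            class = "spec_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict case-class probabilities
#'
#' @param model A fitted `spec_model`.
#' @param features Numeric matrix with the same feature count (and order)
#'   as the training matrix.
#' @return Numeric score vector in \code{[0, 1]}, one per row.
#' @export
predict_scores <- function(model, features) {
  if (!inherits(model, "spec_model")) stop("model must be a spec_model")
  if (ncol(features) != model$n_features) {
    stop("feature count mismatch: model expects ", model$n_features,
         ", got ", ncol(features))
  }
  colnames(features) <- model$feature_names
  if (model$family == "rf") {
    p <- stats::predict(model$fit, data = as.data.frame(features),
                        num.threads = 1)$predictions
    scores <- p[, "case"]
  } else {
    scores <- as.numeric(stats::predict(model$fit, newx = features,
                                        type = "response"))
  }
  scores <- pmin(pmax(scores, 0), 1)
  if (any(!is.finite(scores))) stop("non-finite scores produced")
  unname(scores)
}

#' Per-feature importance weights
#'
#' Model-native importance: Gini impurity decrease for the forest family,
#' absolute standardized coefficients for the logistic family. Weights are
#' clipped at zero and normalized to sum to 1 whenever any weight is
#' positive.
#'
#' @param model A fitted `spec_model`.
#' @return Non-negative numeric vector, one weight per training feature.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "spec_model")) stop("model must be a spec_model")
  w <- if (model$family == "rf") {
    as.numeric(ranger::importance(model$fit))
  } else {
    as.numeric(abs(stats::coef(model$fit)[-1]))  # drop intercept
  }
  w <- pmax(w, 0)
  if (sum(w) > 0) w <- w / sum(w)
  names(w) <- model$feature_names
  w
}
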