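#' Train a land-cover classifier
#'
#' Fits a classifier on a sample-by-feature table. The default method is a
#' random forest; a nearest-centroid classifier is available behind the same
#' interface for quick, dependency-light runs. Training is seeded and
#' reproducible.
#'
#' @param features numeric matrix or data.frame, samples x features.
#' @param labels integer or factor class labels, one per sample.
#' @param method \code{"random_forest"} or \code{"nearest_centroid"}.
#' @param seed integer seed for the (stochastic) forest fit.
#' @param ntree trees in the forest.
#' @return An object of class \code{lc_classifier}.
#' @export
train_classifier <- function(features, labels,
                             method = c("random_forest", "nearest_centroid"),
                             seed = 1L, ntree = 200L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  if (nrow(features) != length(labels)) {
    stop("one label per sample required", call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("training needs at least two classes", call. = FALSE)
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- if (method == "random_forest") {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    randomForest::randomForest(features, labels, ntree = ntree)
  } else {
    centroids <- apply(features, 2L, function(col) {
      tapply(col, labels, mean)
    })
    matrix(centroids, nrow = nlevels(labels),
           dimnames = list(levels(labels), colnames(features)))
  }
  structure(list(method = method, fit = fit, classes = levels(labels),
                 n_features = ncol(features), seed = seed),
            class = "lc_classifier")
}

#' @export
print.lc_classifier <- function(x, ...) {
  cat(sprintf("<lc_classifier> %s, %d classes, %d features\n",
              x$method, length(x$classes), x$n_features))
  invisible(x)
}

classifier_predict <- function(object, features) {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (ncol(features) != object$n_features) {
    stop("feature count does not match training (", object$n_features,
         " expected)", call. = FALSE)
  }
  if (object$method == "random_forest") {
    as.integer(as.character(stats::predict(object$fit, features)))
  } else {
    d2 <- outer(rowSums(features^2), rowSums(object$fit^2), "+") -
      2 * features %*% t(object$fit)
    as.integer(rownames(object$fit)[max.col(-d2, ties.method = "first")])
  }
}

#' @export
predict.lc_classifier <- function(object, newdata, ...) {
  classifier_predict(object, newdata)
}

#' Predict a land-cover map from a feature stack
#'
#' Applies a trained classifier per pixel; any pixel with a nodata value in
#' any feature band is nodata in the output.
#'
#' @param classifier an \code{lc_classifier}.
#' @param features a \code{raster_stack} of feature bands (band count must
#'   match training).
#' @return a \code{raster_grid} of integer class codes.
#' @export
predict_landcover <- function(classifier, features) {
  if (!inherits(features, "raster_stack")) {
    stop("`features` must be a raster_stack", call. = FALSE)
  }
  if (length(features$layers) != classifier$n_features) {
    stop("feature band count does not match training", call. = FALSE)
  }
  tmpl <- features$layers[[1L]]
  X <- vapply(features$layers, function(g) as.vector(g$values),
              numeric(length(tmpl$values)))
  valid <- Reduce(`&`, lapply(features$layers, grid_valid_mask))
  out <- rep(NA_real_, length(tmpl$values))
  vi <- as.vector(valid)
  if (any(vi)) {
    out[vi] <- classifier_predict(classifier, X[vi, , drop = FALSE])
  }
  grid_like(tmpl, matrix(out, nrow(tmpl$values), ncol(tmpl$values)),
            nodata = NA_real_)
}

#' Confusion matrix of predicted against reference labels
#'
#' @param reference reference (ground-truth) labels.
#' @param predicted predicted labels, same length.
#' @return An object of class \code{confusion_matrix}: an integer matrix
#'   with reference classes as rows and predicted classes as columns, over
#'   the union of labels seen in either vector.
#' @export
confusion_matrix <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted must have equal length", call. = FALSE)
  }
  classes <- sort(unique(c(reference, predicted)))
  ref <- factor(reference, levels = classes)
  pred <- factor(predicted, levels = classes)
  cm <- table(reference = ref, predicted = pred)
  structure(unclass(cm), class = "confusion_matrix")
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy (trace over total), Cohen's kappa
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e), \quad
#'       p_e = \sum_k row_k \cdot col_k / n^2,}
#' and per-class precision (user's accuracy, diag/column) and recall
#' (producer's accuracy, diag/row). Classes with no predicted (reference)
#' samples get \code{NA} precision (recall); when chance agreement is exact
#' (\eqn{p_e = 1}) kappa is undefined and reported as \code{NA}.
#'
#' @param cm a \code{\link{confusion_matrix}} or any square count matrix
#'   (rows = reference).
#' @return list with \code{overall_accuracy}, \code{kappa}, and a
#'   \code{per_class} data.frame of \code{class}, \code{precision},
#'   \code{recall}.
#' @export
accuracy_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  diag_k <- diag(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  p_o <- sum(diag_k) / n
  p_e <- sum(rows * cols) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) NA_real_
           else (p_o - p_e) / (1 - p_e)
  per_class <- data.frame(
    class = if (!is.null(rownames(cm))) rownames(cm)
            else as.character(seq_len(nrow(cm))),
    precision = ifelse(cols > 0, diag_k / cols, NA_real_),
    recall = ifelse(rows > 0, diag_k / rows, NA_real_),
    stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  list(overall_accuracy = p_o, kappa = kappa, per_class = per_class)
}

#' Grassland mask from a land-cover map
#'
#' @param classes a \code{raster_grid} of class codes.
#' @param grassland_code code of the grassland class (default from
#'   \code{\link{landcover_codebook}}).
#' @return a \code{raster_grid} with value 1 on grassland, 0 elsewhere,
#'   nodata preserved. Warns when no grassland pixel exists.
#' @export
grassland_mask <- function(classes,
                           grassland_code = landcover_codebook()[["grassland"]]) {
  stopifnot(is_raster_grid(classes))
  valid <- grid_valid_mask(classes)
  m <- matrix(NA_real_, nrow(classes$values), ncol(classes$values))
  m[valid] <- as.numeric(classes$values[valid] == grassland_code)
  if (!any(m[valid] == 1)) {
    warning("mask is empty: no grassland pixels found", call. = FALSE)
  }
  grid_like(classes, m, nodata = NA_real_)
}

#' Areal class fractions of a land-cover map
#'
#' @param classes a \code{raster_grid} of class codes.
#' @return data.frame of \code{class} code and \code{fraction} of valid
#'   pixels.
#' @export
class_fractions <- function(classes) {
  v <- grid_valid_values(classes)
  tab <- table(v)
  data.frame(class = as.integer(names(tab)),
             fraction = as.numeric(tab) / length(v))
}
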