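#' Extract predictor values at sample points
#'
#' Looks up the three seasonal composites at each point's containing pixel.
#' Points falling outside the raster extent or on nodata cells are excluded,
#' with a message giving the count.
#'
#' @param composites named list of \code{raster_grid}s: \code{ndvi} (maximum
#'   value composite), \code{lst} (seasonal mean), \code{precip} (seasonal
#'   total).
#' @param points data.frame with columns \code{x}, \code{y}.
#' @return data.frame with columns \code{x}, \code{y}, \code{ndvi},
#'   \code{lst}, \code{precip} and attribute \code{n_excluded}.
#' @export
sample_predictors <- function(composites, points) {
  stopifnot(all(c("ndvi", "lst", "precip") %in% names(composites)))
  check_aligned(composites[c("ndvi", "lst", "precip")])
  ref <- composites$ndvi
  tr <- ref$transform
  col <- floor((points$x - tr[["x_origin"]]) / tr[["px"]]) + 1L
  row <- floor((points$y - tr[["y_origin"]]) / tr[["py"]]) + 1L
  inside <- row >= 1L & row <= nrow(ref$values) &
    col >= 1L & col <= ncol(ref$values)
  if (!any(inside)) stop("all points fall outside the raster extent",
                         call. = FALSE)
  idx <- cbind(row[inside], col[inside])
  vals <- lapply(composites[c("ndvi", "lst", "precip")], function(g) {
    v <- g$values
    v[!grid_valid_mask(g)] <- NA_real_
    v[idx]
  })
  ok <- !Reduce(`|`, lapply(vals, is.na))
  out <- data.frame(x = points$x[inside][ok], y = points$y[inside][ok],
                    ndvi = vals$ndvi[ok], lst = vals$lst[ok],
                    precip = vals$precip[ok])
  n_excluded <- nrow(points) - nrow(out)
  if (n_excluded > 0L) {
    message(n_excluded, " point(s) excluded (outside extent or nodata)")
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Fit the AGB estimation model
#'
#' Links field-measured above-ground biomass to the seasonal composites. The
#' default is ordinary least squares on (NDVI, LST, precipitation) — the
#' exact solution of the linear model; a random forest is available behind
#' the same interface.
#'
#' @param X predictor data.frame with columns \code{ndvi}, \code{lst},
#'   \code{precip} (extra columns ignored).
#' @param y measured AGB, g/m2.
#' @param method \code{"linear"} or \code{"random_forest"}.
#' @param seed seed for the stochastic forest fit.
#' @param ntree trees in the forest.
#' @return An object of class \code{agb_model} with fields \code{method},
#'   \code{fit}, \code{coefficients} (linear only), \code{n}.
#' @export
fit_agb_model <- function(X, y, method = c("linear", "random_forest"),
                          seed = 1L, ntree = 300L) {
  method <- match.arg(method)
  vars <- c("ndvi", "lst", "precip")
  if (!all(vars %in% names(X))) {
    stop("X needs columns ndvi, lst, precip", call. = FALSE)
  }
  X <- X[vars]
  if (nrow(X) < 10L) stop("need at least 10 samples", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response",
                                 call. = FALSE)
  if (method == "linear") {
    d <- cbind(agb = y, X)
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < ncol(X) + 1L) {
      stop("predictor matrix is rank-deficient; linear fit is degenerate",
           call. = FALSE)
    }
    fit <- stats::lm(agb ~ ndvi + lst + precip, data = d)
    coefs <- stats::coef(fit)
    names(coefs) <- c("intercept", vars)
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    fit <- randomForest::randomForest(as.matrix(X), y, ntree = ntree)
    coefs <- NULL
  }
  structure(list(method = method, fit = fit, coefficients = coefs,
                 n = nrow(X), predictors = vars, seed = seed),
            class = "agb_model")
}

#' @export
print.agb_model <- function(x, ...) {
  cat(sprintf("<agb_model> %s, n = %d\n", x$method, x$n))
  if (!is.null(x$coefficients)) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

agb_model_predict <- function(model, newdata) {
  newdata <- newdata[model$predictors]
  if (model$method == "linear") {
    unname(stats::predict(model$fit,
                          stats::setNames(newdata, model$predictors)))
  } else {
    unname(stats::predict(model$fit, as.matrix(newdata)))
  }
}

#' @export
predict.agb_model <- function(object, newdata, ...) {
  agb_model_predict(object, newdata)
}

#' Predict a wall-to-wall AGB map
#'
#' Applies a fitted AGB model to the composite rasters; predictions are
#' clipped below at 0 g/m2 (negative biomass is physically meaningless) and
#' nodata propagates from any input band.
#'
#' @param model an \code{agb_model}.
#' @param composites named list of \code{raster_grid}s \code{ndvi},
#'   \code{lst}, \code{precip}.
#' @return a \code{raster_grid} of AGB in g/m2.
#' @export
predict_agb <- function(model, composites) {
  if (!all(model$predictors %in% names(composites))) {
    stop("composites must provide ", paste(model$predictors, collapse = ", "),
         call. = FALSE)
  }
  check_aligned(composites[model$predictors])
  ref <- composites[[model$predictors[[1L]]]]
  valid <- Reduce(`&`, lapply(composites[model$predictors], grid_valid_mask))
  newdata <- data.frame(lapply(composites[model$predictors], function(g) {
    as.vector(g$values)
  }))
  out <- rep(NA_real_, length(ref$values))
  vi <- as.vector(valid)
  out[vi] <- pmax(agb_model_predict(model, newdata[vi, , drop = FALSE]), 0)
  grid_like(ref, matrix(out, nrow(ref$values), ncol(ref$values)),
            nodata = NA_real_)
}

#' Validate AGB predictions against measurements
#'
#' @param predicted model predictions at the sample points, g/m2.
#' @param measured field measurements, g/m2.
#' @return list with \code{r} (Pearson correlation; \code{NA} with a warning
#'   when either vector has zero variance), \code{rmse} (g/m2) and \code{n}.
#' @export
validate_agb <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  n <- length(measured)
  if (n < 2L) stop("need at least 2 points to validate", call. = FALSE)
  rmse <- sqrt(mean((predicted - measured)^2))
  r <- if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(predicted, measured)
  }
  list(r = r, rmse = rmse, n = n)
}

#' Five-class grassland productivity map
#'
#' Bins AGB into the standard productivity classes: extremely low
#' (< 200 g/m2), low [200, 250), moderate [250, 300), high [300, 350],
#' extremely high (> 350). Interior breakpoints are left-closed (a value on
#' a breakpoint falls in the upper class); the top class is strictly above
#' 350.
#'
#' @param agb a \code{raster_grid} of AGB in g/m2 (non-negative).
#' @return a \code{raster_grid} of codes 1 (extremely low) to 5 (extremely
#'   high).
#' @export
classify_productivity <- function(agb) {
  stopifnot(is_raster_grid(agb))
  valid <- grid_valid_mask(agb)
  if (any(agb$values[valid] < 0)) {
    stop("negative AGB is invalid; clip predictions at 0 first",
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(agb$values), ncol(agb$values))
  v <- agb$values[valid]
  code <- findInterval(v, c(200, 250, 300)) + 1
  code[v > 350] <- 5
  out[valid] <- code
  grid_like(agb, out, nodata = NA_real_)
}

#' Productivity class labels
#' @return named character vector mapping codes 1-5 to class names.
#' @export
productivity_labels <- function() {
  c(`1` = "extremely low", `2` = "low", `3` = "moderate",
    `4` = "high", `5` = "extremely high")
}
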