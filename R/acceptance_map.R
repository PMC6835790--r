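#' Quadratic acceptance model
#'
#' Danzart-style quadratic response surface over the consumer map:
#' f(d1, d2) = a0 + a1 d1 + a2 d2 + a3 d1^2 + a4 d2^2 + a5 d1 d2,
#' fitted by ordinary least squares to the per-consumer grades.
#'
#' @param embedding An `lpl_embedding`.
#' @param grades Numeric vector of grades g_i, one per consumer, in the
#'   embedding's consumer order.
#' @return An object of class `lpl_qua` with `alpha` (named a0..a5), the
#'   fitted `lm` object, and training `fitted` values.
#' @export
fit_quadratic <- function(embedding, grades) {
  stopifnot(inherits(embedding, "lpl_embedding"),
            length(grades) == nrow(embedding$coords))
  n <- length(grades)
  if (n < 6L) {
    stop("quadratic model needs at least 6 consumers (it has 6 coefficients)",
         call. = FALSE)
  }
  df <- data.frame(g = as.numeric(grades),
                   d1 = embedding$coords[, 1], d2 = embedding$coords[, 2])
  X <- stats::model.matrix(~ d1 + d2 + I(d1^2) + I(d2^2) + I(d1 * d2), df)
  rk <- qr(X)$rank
  if (rk < 6L) {
    stop(sprintf(
      "rank-deficient quadratic design (rank %d of 6): consumer coordinates are degenerate (e.g. collinear)",
      rk), call. = FALSE)
  }
  fit <- stats::lm(g ~ d1 + d2 + I(d1^2) + I(d2^2) + I(d1 * d2), data = df)
  alpha <- stats::setNames(stats::coef(fit), paste0("a", 0:5))
  structure(list(alpha = alpha, lm = fit, fitted = stats::fitted(fit),
                 regressor = "QUA"),
            class = c("lpl_qua", "lpl_regressor"))
}

#' @export
predict.lpl_qua <- function(object, newdata, ...) {
  pts <- matrix(as.numeric(newdata), ncol = 2L)
  a <- object$alpha
  a[1] + a[2] * pts[, 1] + a[3] * pts[, 2] + a[4] * pts[, 1]^2 +
    a[5] * pts[, 2]^2 + a[6] * pts[, 1] * pts[, 2]
}

#' Default RBF width for the support-vector acceptance model
#'
#' gamma = 1 / (d * Var(coords)) with d = 2 map dimensions and Var the
#' variance of the pooled coordinate entries — the variance-scaled kernel
#' width convention of mainstream SVR implementations (scikit-learn's
#' `gamma = "scale"`), so the kernel length scale follows the spread of the
#' map. [svm_pairwise_gamma()] is a more conservative alternative based on
#' the mean pairwise squared distance; it yields a wider kernel and
#' visibly smoother (but less faithful) landscapes.
#'
#' @param coords n x 2 coordinate matrix.
#' @return Positive scalar gamma.
#' @export
svm_default_gamma <- function(coords) {
  coords <- as.matrix(coords)
  # mean per-axis variance (axis-wise centering): invariant under rigid
  # motions of the map, and identical to the pooled-variance convention on
  # centered embeddings
  v <- mean(sweep(coords, 2L, colMeans(coords))^2)
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(coords) * v)
}

#' @rdname svm_default_gamma
#' @export
svm_pairwise_gamma <- function(coords) {
  coords <- as.matrix(coords)
  d2 <- stats::dist(coords)^2
  m <- mean(d2)
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m)
}

#' Support-vector acceptance model
#'
#' Epsilon-insensitive support-vector regression with a Gaussian (RBF)
#' kernel over the 2-D consumer coordinates, predicting one evaluation's
#' grades. Deterministic given inputs and hyperparameters.
#'
#' @param embedding An `lpl_embedding`.
#' @param grades Numeric grades, one per consumer.
#' @param cost SVR cost C (> 0, default 1).
#' @param epsilon Insensitivity tube half-width (> 0, default 0.1 scale
#'   units).
#' @param gamma RBF width; default [svm_default_gamma()] of the coordinates.
#' @return An object of class `lpl_svm` wrapping the fitted
#'   [e1071::svm()] model with the hyperparameters recorded.
#' @export
fit_svm <- function(embedding, grades, cost = 1, epsilon = 0.1, gamma = NULL) {
  stopifnot(inherits(embedding, "lpl_embedding"),
            length(grades) == nrow(embedding$coords))
  if (length(grades) < 2L) stop("SVR needs at least 2 consumers", call. = FALSE)
  if (!is.finite(cost) || cost <= 0 || !is.finite(epsilon) || epsilon <= 0) {
    stop("invalid SVR hyperparameters: cost and epsilon must be positive",
         call. = FALSE)
  }
  if (is.null(gamma)) gamma <- svm_default_gamma(embedding$coords)
  if (!is.finite(gamma) || gamma <= 0) {
    stop("invalid SVR hyperparameter: gamma must be positive", call. = FALSE)
  }
  g <- as.numeric(grades)
  if (stats::sd(g) == 0) {
    # constant target: e1071::svm cannot scale y; represent exactly
    model <- NULL
  } else {
    model <- e1071::svm(x = embedding$coords, y = g, type = "eps-regression",
                        kernel = "radial", cost = cost, epsilon = epsilon,
                        gamma = gamma, scale = FALSE)
  }
  fitted <- if (is.null(model)) rep(g[1], length(g)) else
    as.numeric(stats::predict(model, embedding$coords))
  structure(
    list(model = model, constant = if (is.null(model)) g[1] else NULL,
         fitted = fitted, regressor = "SVM",
         hyperparams = list(cost = cost, epsilon = epsilon, gamma = gamma)),
    class = c("lpl_svm", "lpl_regressor")
  )
}

#' @export
predict.lpl_svm <- function(object, newdata, ...) {
  pts <- matrix(as.numeric(newdata), ncol = 2L)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(pts)))
  colnames(pts) <- c("dim1", "dim2")
  as.numeric(stats::predict(object$model, pts))
}

#' Fit an acceptance model by name
#'
#' @param embedding An `lpl_embedding`.
#' @param grades Numeric grades.
#' @param regressor `"SVM"` or `"QUA"`.
#' @param ... Passed to [fit_svm()] (hyperparameters).
#' @return An `lpl_regressor`.
#' @export
fit_acceptance <- function(embedding, grades, regressor = c("SVM", "QUA"), ...) {
  regressor <- match.arg(regressor)
  switch(regressor,
         SVM = fit_svm(embedding, grades, ...),
         QUA = fit_quadratic(embedding, grades))
}

#' Percentage error of an acceptance model
#'
#' The training mean absolute error scaled to 0--100:
#' 100 * MAE / n_points, where n_points is the number of categories of the
#' evaluation scale (9 hedonic, 5 JAR). Computed on the training consumers
#' themselves — a descriptive fit measure, not a generalization estimate.
#'
#' @param model An `lpl_regressor`.
#' @param embedding The embedding the model was fitted on.
#' @param grades The training grades.
#' @param scale The governing `lpl_scale`.
#' @param use_range Divide by the scale range (`max - min`) instead of the
#'   category count.
#' @return Number in `[0, 100]`.
#' @export
percentage_error <- function(model, embedding, grades, scale,
                             use_range = FALSE) {
  stopifnot(inherits(model, "lpl_regressor"), inherits(scale, "lpl_scale"),
            length(grades) == nrow(embedding$coords))
  g <- as.numeric(grades)
  if (any(g < scale$min_value | g > scale$max_value)) {
    stop(sprintf("grades fall outside the %s scale [%d, %d]",
                 scale$name, scale$min_value, scale$max_value), call. = FALSE)
  }
  preds <- predict(model, embedding$coords)
  mae <- mean(abs(preds - g))
  denom <- if (use_range) scale$max_value - scale$min_value else scale$n_points
  100 * mae / denom
}

#' Acceptance surface on a grid
#'
#' Evaluates a fitted acceptance model on every node of the shared grid and
#' bundles it with its evaluation identity and percentage error.
#'
#' @param model An `lpl_regressor`.
#' @param grid An `lpl_grid` (shared with the density field).
#' @param embedding,grades,scale Training context, used to compute the
#'   percentage error and stored with the surface.
#' @param evaluation_id Length-2 character `(product, measure)`.
#' @return An object of class `lpl_surface` with `grid`, `values`
#'   (length(x) x length(y)), `regressor`, `evaluation_id`,
#'   `percentage_error`, `grades`.
#' @export
evaluate_surface <- function(model, grid, embedding, grades, scale,
                             evaluation_id = c(product = "", measure = "")) {
  stopifnot(inherits(grid, "lpl_grid"))
  bb <- apply(embedding$coords, 2L, range)
  if (min(grid$x) > bb[1, 1] || max(grid$x) < bb[2, 1] ||
      min(grid$y) > bb[1, 2] || max(grid$y) < bb[2, 2]) {
    warning("grid does not cover the embedding bounding box; surface values outside the grid are extrapolations")
  }
  nodes <- cbind(rep(grid$x, times = length(grid$y)),
                 rep(grid$y, each = length(grid$x)))
  vals <- matrix(predict(model, nodes), length(grid$x), length(grid$y))
  pe <- percentage_error(model, embedding, grades, scale)
  structure(
    list(grid = grid, values = vals, regressor = model$regressor,
         evaluation_id = evaluation_id, percentage_error = pe,
         grades = as.numeric(grades), scale = scale, model = model),
    class = "lpl_surface"
  )
}

#' Small grid search over SVR hyperparameters
#'
#' Optional helper (off by default everywhere): scores a small grid of
#' (cost, epsilon, gamma) combinations by training percentage error and
#' returns the best. Results with the default hyperparameters remain the
#' package's deterministic reference.
#'
#' @param embedding,grades,scale As in [percentage_error()].
#' @param costs,epsilons,gammas Candidate values; `NULL` gamma means the
#'   data-driven default.
#' @return List with `best` (hyperparameter list) and `results` tibble.
#' @export
svm_grid_search <- function(embedding, grades, scale,
                            costs = c(0.5, 1, 2, 4),
                            epsilons = c(0.05, 0.1, 0.2),
                            gammas = NULL) {
  if (is.null(gammas)) {
    g0 <- svm_default_gamma(embedding$coords)
    gammas <- g0 * c(0.5, 1, 2)
  }
  grid <- expand.grid(cost = costs, epsilon = epsilons, gamma = gammas)
  grid$error <- vapply(seq_len(nrow(grid)), function(i) {
    m <- fit_svm(embedding, grades, cost = grid$cost[i],
                 epsilon = grid$epsilon[i], gamma = grid$gamma[i])
    percentage_error(m, embedding, grades, scale)
  }, numeric(1))
  best <- grid[which.min(grid$error), ]
  list(best = as.list(best[, c("cost", "epsilon", "gamma")]),
       results = tibble::as_tibble(grid))
}
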