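#' @title 2-D consumer embeddings
#' @description Internal constructor for the embedding container shared by
#'   all mapping techniques.
#' @noRd
new_embedding <- function(consumer_ids, coords, technique, data_mode,
                          stress = NULL, explained_variance = NULL,
                          product_coords = NULL, segments = NULL,
                          meta = list()) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) == length(consumer_ids),
            all(is.finite(coords)))
  dimnames(coords) <- list(consumer_ids, c("dim1", "dim2"))
  if (!is.null(stress)) stopifnot(stress >= 0)
  if (!is.null(explained_variance)) {
    stopifnot(length(explained_variance) == 2L,
              all(explained_variance >= 0), all(explained_variance <= 1),
              diff(explained_variance) <= 1e-12)
  }
  structure(
    list(consumer_ids = consumer_ids, coords = coords, technique = technique,
         data_mode = data_mode, stress = stress,
         explained_variance = explained_variance,
         product_coords = product_coords, segments = segments, meta = meta),
    class = "lpl_embedding"
  )
}

#' @export
print.lpl_embedding <- function(x, ...) {
  cat(sprintf("<lpl_embedding> %s on %s data, %d consumers\n",
              x$technique, x$data_mode, nrow(x$coords)))
  if (!is.null(x$stress)) cat(sprintf("  Kruskal stress-1: %.4g\n", x$stress))
  if (!is.null(x$explained_variance)) {
    cat(sprintf("  explained variance: %.1f%% + %.1f%%\n",
                100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  }
  invisible(x)
}

# Fix the sign of each component so the largest-|loading| entry is positive;
# flips scores (and any companion matrix) consistently.
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal-component consumer map
#'
#' Projects the consumer vectors onto the first two principal components of
#' the column-centered (optionally standardized) consumer matrix. The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making the map reproducible across runs and platforms.
#'
#' @param vectors An `lpl_vectors` object from [to_vectors()].
#' @param standardize Scale columns to unit variance before the PCA
#'   (default `FALSE`; hedonic and signed JAR values share comparable
#'   ranges).
#' @return An `lpl_embedding` with `explained_variance` for the two
#'   components.
#' @export
embed_pca <- function(vectors, standardize = FALSE) {
  stopifnot(inherits(vectors, "lpl_vectors"))
  X <- vectors$matrix
  if (nrow(X) < 3L) stop("PCA map needs at least 3 consumers", call. = FALSE)
  if (ncol(X) < 2L) stop("PCA map needs at least 2 dimensions", call. = FALSE)
  tot_var <- sum(apply(X, 2L, stats::var))
  if (tot_var < .Machine$double.eps) {
    stop("degenerate input: consumer vectors have zero variance", call. = FALSE)
  }
  if (standardize) {
    keep <- apply(X, 2L, stats::sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  fixed <- fix_signs(pc$rotation[, 1:2, drop = FALSE],
                     pc$x[, 1:2, drop = FALSE])
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  new_embedding(vectors$consumer_ids, fixed$scores, "PCA", vectors$data_mode,
                explained_variance = ev, segments = vectors$segments,
                meta = list(standardize = standardize))
}

#' Internal-preference-mapping consumer map
#'
#' The classic IPM construction: a PCA of the products-by-consumers overall
#' liking matrix (products as observations, consumers as variables,
#' columns centered). Products become points (their scores on the first two
#' components); each consumer becomes a preference vector, its loading on
#' each component scaled by the variance of the product scores on that
#' component. The vector's direction points toward preferred products and
#' its length grows with how sharply the consumer discriminates.
#'
#' @param table An `lpl_table` (only overall liking is used, by the method's
#'   definition).
#' @param standardize Standardize consumers (columns) to unit variance
#'   before the PCA (default `FALSE`).
#' @return An `lpl_embedding` with `product_coords` (P x 2).
#' @export
embed_ipm <- function(table, standardize = FALSE) {
  stopifnot(inherits(table, "lpl_table"))
  vec <- to_vectors(table, "OL")
  M <- t(vec$matrix) # P x n: products as rows, consumers as columns
  rownames(M) <- sub("\\|overall_liking$", "", rownames(M))
  if (nrow(M) < 3L) stop("IPM needs at least 3 products", call. = FALSE)
  if (any(apply(M, 2L, stats::sd) == 0) && standardize) {
    stop("cannot standardize: a consumer gave identical grades to all products",
         call. = FALSE)
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = standardize)
  ncomp <- min(2L, ncol(pc$x))
  if (ncomp < 2L) stop("IPM rank too low for a 2-D map", call. = FALSE)
  fixed <- fix_signs(pc$rotation[, 1:2, drop = FALSE],
                     pc$x[, 1:2, drop = FALSE])
  prod_scores <- fixed$scores
  comp_var <- apply(prod_scores, 2L, stats::var)
  consumer_coords <- sweep(fixed$loadings, 2L, comp_var, `*`)
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  dimnames(prod_scores) <- list(rownames(M), c("dim1", "dim2"))
  new_embedding(vec$consumer_ids, consumer_coords, "IPM", "OL",
                explained_variance = ev, product_coords = prod_scores,
                segments = vec$segments,
                meta = list(standardize = standardize,
                            product_scaling = "per-component variance"))
}

#' Metric multidimensional-scaling consumer map
#'
#' Embeds consumers in the plane so that inter-consumer Euclidean distances
#' in the evaluation space are preserved as well as possible. Uses classical
#' (Torgerson) scaling as the starting configuration, refined by SMACOF
#' majorization of the raw stress; the raw stress is non-increasing across
#' iterations. Fit quality is reported as normalized Kruskal stress-1,
#' sqrt(sum (d_ij - dhat_ij)^2 / sum d_ij^2). The final configuration is
#' rotated to its own principal axes with fixed signs, removing the
#' rotation/reflection indeterminacy.
#'
#' @param vectors An `lpl_vectors` object.
#' @param seed Integer; used only to jitter a degenerate (rank-deficient)
#'   starting configuration.
#' @param max_iter,tol Majorization iteration cap and relative raw-stress
#'   convergence tolerance.
#' @return An `lpl_embedding` with `stress` (Kruskal stress-1) and the
#'   per-iteration raw-stress trace in `meta$stress_trace`.
#' @export
embed_mds <- function(vectors, seed = 1L, max_iter = 300L, tol = 1e-10) {
  stopifnot(inherits(vectors, "lpl_vectors"))
  X <- vectors$matrix
  n <- nrow(X)
  if (n < 3L) stop("MDS map needs at least 3 consumers", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  if (max(D) < .Machine$double.eps) {
    stop("degenerate input: all consumer vectors are identical", call. = FALSE)
  }
  init <- suppressWarnings(stats::cmdscale(D, k = 2L))
  if (ncol(init) < 2L || any(apply(init, 2L, stats::sd) < 1e-12)) {
    init <- cbind(init, 0)[, 1:2, drop = FALSE]
    init <- init + withr::with_seed(seed,
      matrix(stats::rnorm(2L * n, sd = 1e-6 * max(D)), n, 2L))
  }
  Y <- init
  DY <- as.matrix(stats::dist(Y))
  raw_stress <- function(DY) sum((D - DY)[upper.tri(D)]^2)
  trace <- raw_stress(DY)
  for (it in seq_len(max_iter)) {
    # Guttman transform: Y_new = (1/n) B(Y) Y with B from the current distances
    ratio <- ifelse(DY > 0, D / DY, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Y_new <- B %*% Y / n
    DY_new <- as.matrix(stats::dist(Y_new))
    s_new <- raw_stress(DY_new)
    trace <- c(trace, s_new)
    done <- (trace[length(trace) - 1L] - s_new) <=
      tol * max(trace[length(trace) - 1L], .Machine$double.eps)
    Y <- Y_new
    DY <- DY_new
    if (done) break
  }
  # canonical orientation: principal axes of the final configuration
  Y <- scale(Y, scale = FALSE)
  pc <- stats::prcomp(Y, center = FALSE)
  rot <- pc$rotation
  if (ncol(rot) < 2L) rot <- cbind(rot, c(-rot[2, 1], rot[1, 1]))
  Y <- Y %*% rot
  for (j in 1:2) {
    k <- which.max(abs(Y[, j]))
    if (Y[k, j] < 0) Y[, j] <- -Y[, j]
  }
  DY <- as.matrix(stats::dist(Y))
  stress1 <- sqrt(sum((D - DY)[upper.tri(D)]^2) / sum(D[upper.tri(D)]^2))
  new_embedding(vectors$consumer_ids, Y, "MDS", vectors$data_mode,
                stress = stress1, segments = vectors$segments,
                meta = list(stress_trace = trace, iterations = length(trace) - 1L,
                            seed = seed))
}

#' Segment separation of an embedding
#'
#' Ratio of the between-centroid distance to the largest within-segment
#' root-mean-square spread; larger means the two segments are more clearly
#' separated on the map. Defined for exactly two segments.
#'
#' @param embedding An `lpl_embedding`.
#' @param labels Segment labels (defaults to the embedding's own).
#' @return A positive number.
#' @export
segment_separation <- function(embedding, labels = embedding$segments) {
  stopifnot(inherits(embedding, "lpl_embedding"), !is.null(labels))
  labels <- as.character(labels)
  levs <- lex_sort(labels)
  stopifnot(length(levs) == 2L)
  cent <- lapply(levs, function(l) colMeans(embedding$coords[labels == l, , drop = FALSE]))
  spread <- vapply(levs, function(l) {
    pts <- embedding$coords[labels == l, , drop = FALSE]
    c0 <- colMeans(pts)
    sqrt(mean(rowSums(sweep(pts, 2L, c0)^2)))
  }, numeric(1))
  between <- sqrt(sum((cent[[1]] - cent[[2]])^2))
  between / max(spread)
}
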