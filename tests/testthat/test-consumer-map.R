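test_that("PCA map is lossless on intrinsically 2-D data", {
  withr::with_seed(7, {
    plane <- matrix(rnorm(20 * 2), 20, 2)
    basis <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
    X <- plane %*% t(basis) # 2-D configuration embedded in R^6
  })
  vec <- structure(list(consumer_ids = sprintf("c%02d", 1:20), matrix = X,
                        data_mode = "OL", column_labels = NULL,
                        segments = NULL), class = "lpl_vectors")
  emb <- embed_pca(vec)
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(X)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(emb$explained_variance), 1, tolerance = 1e-10)
})

test_that("PCA map is deterministic, order-invariant and sign-fixed", {
  tab <- make_random_table(C = 10, P = 4, A = 2, seed = 2)
  vec <- to_vectors(tab, "OLJAR")
  e1 <- embed_pca(vec)
  e2 <- embed_pca(vec)
  expect_identical(e1$coords, e2$coords)
  # duplicated consumers land on identical coordinates
  dup <- vec
  dup$matrix <- rbind(vec$matrix, vec$matrix[3, , drop = FALSE])
  dup$consumer_ids <- c(vec$consumer_ids, "zz_dup")
  rownames(dup$matrix) <- dup$consumer_ids
  e3 <- embed_pca(dup)
  expect_equal(unname(e3$coords[3, ]), unname(e3$coords[11, ]))
  # zero variance input is rejected
  flat <- vec
  flat$matrix[] <- 4
  expect_error(embed_pca(flat), "zero variance")
})

test_that("PCA 2-D projection beats random rank-2 projections (Eckart-Young)", {
  tab <- make_random_table(C = 15, P = 5, A = 3, seed = 6)
  X <- scale(to_vectors(tab, "OLJAR")$matrix, scale = FALSE)
  pc <- prcomp(X, center = FALSE)
  recon_err <- function(Q) sum((X - X %*% Q %*% t(Q))^2)
  err_pca <- recon_err(pc$rotation[, 1:2])
  withr::with_seed(31, {
    for (rep in 1:5) {
      Q <- qr.Q(qr(matrix(rnorm(ncol(X) * 2), ncol(X), 2)))
      expect_lte(err_pca, recon_err(Q) + 1e-9)
    }
  })
})

test_that("IPM matches a hand-computed eigendecomposition on a toy panel", {
  # 3 products x 4 consumers of overall liking
  M <- matrix(c(2, 5, 8,
                3, 5, 7,
                8, 5, 2,
                5, 6, 4), nrow = 3, ncol = 4,
              dimnames = list(paste0("p", 1:3), paste0("c", 1:4)))
  df <- expand.grid(product_id = rownames(M), consumer_id = colnames(M),
                    stringsAsFactors = FALSE)
  df$measure <- "overall_liking"
  df$value <- M[cbind(df$product_id, df$consumer_id)]
  emb <- embed_ipm(evaluation_table(df))

  # oracle: spectral decomposition (via SVD) of the centered grade matrix
  Mc <- scale(M, scale = FALSE)
  sv <- svd(Mc)
  scores <- sv$u %*% diag(sv$d) # product coordinates
  loadings <- sv$v
  for (j in 1:2) { # apply the package's sign convention
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j]
    }
  }
  expect_equal(unname(emb$product_coords), scores[, 1:2], tolerance = 1e-10)
  comp_var <- apply(scores[, 1:2], 2, var)
  expect_equal(unname(emb$coords), sweep(loadings[, 1:2], 2, comp_var, `*`),
               tolerance = 1e-10)
})

test_that("IPM collapses identical consumers and needs 3 products", {
  df <- expand.grid(consumer_id = paste0("c", 1:4),
                    product_id = paste0("p", 1:3),
                    stringsAsFactors = FALSE)
  df$measure <- "overall_liking"
  df$value <- c(2, 5, 8)[match(df$product_id, paste0("p", 1:3))]
  emb <- embed_ipm(evaluation_table(df)) # all consumers identical
  expect_lt(max(dist(emb$coords)), 1e-10)
  two <- make_random_table(C = 5, P = 2, A = 0)
  expect_error(embed_ipm(two), "at least 3 products")
})

test_that("MDS reproduces intrinsically 2-D configurations with ~zero stress", {
  withr::with_seed(12, {
    plane <- matrix(rnorm(15 * 2), 15, 2)
    basis <- qr.Q(qr(matrix(rnorm(8 * 2), 8, 2)))
    X <- plane %*% t(basis)
  })
  vec <- structure(list(consumer_ids = sprintf("c%02d", 1:15), matrix = X,
                        data_mode = "OLJAR", column_labels = NULL,
                        segments = NULL), class = "lpl_vectors")
  emb <- embed_mds(vec, seed = 1)
  expect_lte(emb$stress, 1e-6)
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(X)),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("MDS raw stress is monotone and beats the classical-scaling start", {
  withr::with_seed(3, X <- matrix(rnorm(12 * 10), 12, 10))
  vec <- structure(list(consumer_ids = sprintf("c%02d", 1:12), matrix = X,
                        data_mode = "OLJAR", column_labels = NULL,
                        segments = NULL), class = "lpl_vectors")
  emb <- embed_mds(vec, seed = 2)
  trace <- emb$meta$stress_trace
  expect_true(all(diff(trace) <= 1e-9))
  # oracle: Kruskal stress-1 of plain classical (Torgerson) scaling
  D <- as.matrix(dist(X))
  Y0 <- cmdscale(D, k = 2)
  s0 <- sqrt(sum((D - as.matrix(dist(Y0)))[upper.tri(D)]^2) /
               sum(D[upper.tri(D)]^2))
  expect_lte(emb$stress, s0 + 1e-12)
  # degenerate input
  same <- vec
  same$matrix[] <- 1
  expect_error(embed_mds(same), "identical")
})

test_that("MDS is reproducible and order-invariant given input and seed", {
  tab <- make_random_table(C = 9, P = 4, A = 2, seed = 8)
  vec <- to_vectors(tab, "OLJAR")
  expect_identical(embed_mds(vec, seed = 5)$coords,
                   embed_mds(vec, seed = 5)$coords)
})

test_that("maps separate the designed segments; JAR-fed maps see segments IPM cannot", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 13))
  vec <- to_vectors(tab, "OLJAR")
  for (emb in list(embed_pca(vec), embed_mds(vec, seed = 13), embed_ipm(tab))) {
    expect_gt(segment_separation(emb), 2) # centroids far beyond the spread
  }
  # mechanism: when segments share their overall-liking profile and differ
  # only in attribute perceptions, the OL-only IPM map cannot separate them
  # while an attribute-fed map can
  jar_tab <- make_jar_only_design(noise_sd = 0.5, seed = 13)
  sep_ipm <- segment_separation(embed_ipm(jar_tab))
  sep_pca_jar <- segment_separation(embed_pca(to_vectors(jar_tab, "JAR")))
  expect_lt(sep_ipm, 1)
  expect_gt(sep_pca_jar, 3)
  expect_gt(sep_pca_jar, 5 * sep_ipm)
})
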