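# Fixtures built in code: small panels and embeddings used across tests.

# A complete random panel: C consumers x P products x (overall liking + A
# attributes), values drawn uniformly on each scale.
make_random_table <- function(C = 8, P = 4, A = 2, seed = 1,
                              segment = NULL) {
  attrs <- if (A > 0) paste0("attr", seq_len(A)) else character()
  grid <- expand.grid(
    consumer_id = sprintf("c%02d", seq_len(C)),
    product_id = sprintf("p%d", seq_len(P)),
    measure = c("overall_liking", attrs),
    stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    grid$value <- ifelse(grid$measure == "overall_liking",
                         sample(1:9, nrow(grid), replace = TRUE),
                         sample(-2:2, nrow(grid), replace = TRUE))
  })
  if (!is.null(segment)) grid$segment <- segment[match(grid$consumer_id,
                                                       sprintf("c%02d", seq_len(C)))]
  evaluation_table(grid)
}

# An embedding at given 2-D coordinates, bypassing any mapping technique.
make_embedding <- function(coords, segments = NULL) {
  coords <- as.matrix(coords)
  ids <- sprintf("c%03d", seq_len(nrow(coords)))
  emb <- lpland:::new_embedding(ids, coords, technique = "PCA",
                                data_mode = "OL", segments = segments)
  emb
}

# A quadratic model object with known coefficients (for arithmetic checks).
make_qua <- function(alpha) {
  structure(list(alpha = stats::setNames(alpha, paste0("a", 0:5)),
                 regressor = "QUA"),
            class = c("lpl_qua", "lpl_regressor"))
}

# Independent normal-equations solve of the quadratic least-squares fit.
oracle_quadratic <- function(coords, g) {
  d1 <- coords[, 1]; d2 <- coords[, 2]
  X <- cbind(1, d1, d2, d1^2, d2^2, d1 * d2)
  as.numeric(solve(t(X) %*% X, t(X) %*% g))
}

# Two-segment panel identical to the packaged design except that both
# segments share one flat overall-liking profile (segments differ only in
# their JAR attribute perceptions).
make_jar_only_design <- function(noise_sd = 0.5, seed = 1) {
  prof <- experiment1_profiles()
  prof$mean[prof$measure == "overall_liking"] <- 6
  mk <- function(seg) {
    segment_profile(seg, 50L, prof[prof$segment == seg,
                                   c("product_id", "measure", "mean")])
  }
  simulate_panel(simulation_spec(list(mk("women"), mk("men")),
                                 noise_sd = noise_sd, seed = seed))
}

# Cluster-label agreement with truth, maximized over label permutations
# (two clusters): fraction of consumers assigned to the majority-matching
# cluster.
label_agreement <- function(labels, truth) {
  tab <- table(labels, truth)
  if (nrow(tab) != 2L || ncol(tab) != 2L) return(0)
  max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
}
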