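#' The fourteen technique/data combinations
#'
#' Every admissible combination of map technique (IPM, PCA, MDS), data mode
#' (OL, JAR, OLJAR) and acceptance regressor (QUA, SVM). IPM is defined on
#' overall liking only, so it pairs with OL alone:
#' {IPM_OL, PCA_OL, PCA_JAR, PCA_OLJAR, MDS_OL, MDS_JAR, MDS_OLJAR} x
#' {QUA, SVM} = 14. Labels follow the `TECH_MODE_REG` convention.
#'
#' @return A 14-row tibble with columns `map_technique`, `data_mode`,
#'   `regressor`, `label`, in a fixed deterministic order.
#' @export
enumerate_combos <- function() {
  maps <- rbind(
    data.frame(map_technique = "IPM", data_mode = "OL"),
    expand.grid(data_mode = c("OL", "JAR", "OLJAR"),
                map_technique = c("PCA", "MDS"),
                stringsAsFactors = FALSE)[, c("map_technique", "data_mode")]
  )
  out <- merge(maps, data.frame(regressor = c("QUA", "SVM")), by = NULL)
  out$label <- paste(out$map_technique, out$data_mode, out$regressor, sep = "_")
  out <- out[lex_order(match(out$map_technique, c("IPM", "PCA", "MDS")),
                       match(out$data_mode, c("OL", "JAR", "OLJAR")),
                       out$regressor), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Parse a combination label
#'
#' @param label A `TECH_MODE_REG` string, e.g. `"MDS_OLJAR_SVM"`.
#' @return List with `map_technique`, `data_mode`, `regressor`.
#' @export
parse_combo <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 3L ||
      !(parts[1] %in% c("IPM", "PCA", "MDS")) ||
      !(parts[2] %in% c("OL", "JAR", "OLJAR")) ||
      !(parts[3] %in% c("QUA", "SVM")) ||
      (parts[1] == "IPM" && parts[2] != "OL")) {
    stop("unknown combination label: ", label, call. = FALSE)
  }
  list(map_technique = parts[1], data_mode = parts[2], regressor = parts[3])
}

#' Build a consumer map for one technique/data combination
#'
#' @param table An `lpl_table`.
#' @param map_technique `"IPM"`, `"PCA"` or `"MDS"`.
#' @param data_mode `"OL"`, `"JAR"` or `"OLJAR"` (ignored for IPM, which is
#'   OL by definition).
#' @param seed Passed to [embed_mds()].
#' @param standardize Passed to the PCA-based techniques.
#' @return An `lpl_embedding`.
#' @export
build_map <- function(table, map_technique = c("MDS", "PCA", "IPM"),
                      data_mode = c("OLJAR", "OL", "JAR"), seed = 1L,
                      standardize = FALSE) {
  map_technique <- match.arg(map_technique)
  if (map_technique == "IPM") {
    return(embed_ipm(table, standardize = standardize))
  }
  data_mode <- match.arg(data_mode)
  vec <- to_vectors(table, data_mode)
  switch(map_technique,
         PCA = embed_pca(vec, standardize = standardize),
         MDS = embed_mds(vec, seed = seed))
}

# Every scored evaluation of a table: each product's overall liking plus
# each product x attribute JAR.
list_evaluations <- function(table) {
  products <- table_products(table)
  measures <- lex_sort(table$measure)
  expand.grid(measure = measures, product_id = products,
              stringsAsFactors = FALSE)[, c("product_id", "measure")]
}

# grades of one evaluation, in lexicographic consumer order
evaluation_grades <- function(table, product, measure) {
  sub <- table[table$product_id == product & table$measure == measure, ]
  sub$value[lex_order(sub$consumer_id)]
}

#' Benchmark the fourteen combinations by percentage error
#'
#' For every combination: build the consumer map, fit one acceptance model
#' per evaluation (each product's overall liking on the 9-point hedonic
#' scale; each product x attribute on the 5-point JAR scale), and average
#' the percentage errors per evaluation family. Combinations are ranked by
#' the average of the two family means (ties broken lexicographically by
#' label).
#'
#' @param table An `lpl_table` with overall liking and at least one
#'   attribute.
#' @param seed Seed forwarded to the MDS maps.
#' @param svm_params Optional list of SVR hyperparameters
#'   (`cost`, `epsilon`, `gamma`).
#' @return An object of class `lpl_benchmark`: tibble `results` with one
#'   row per combination (`label`, `error_ol`, `error_jar`, `error_avg`,
#'   `rank`), plus the per-evaluation error matrix in `errors`.
#' @export
run_benchmark <- function(table, seed = 1L, svm_params = list()) {
  stopifnot(inherits(table, "lpl_table"))
  if (length(table_attributes(table)) < 1L) {
    stop("benchmark requires at least one JAR attribute", call. = FALSE)
  }
  scales <- attr(table, "scales")
  combos <- enumerate_combos()
  evals <- list_evaluations(table)
  maps <- unique(combos[, c("map_technique", "data_mode")])
  embeddings <- list()
  for (i in seq_len(nrow(maps))) {
    key <- paste(maps$map_technique[i], maps$data_mode[i], sep = "_")
    embeddings[[key]] <- tryCatch(
      build_map(table, maps$map_technique[i], maps$data_mode[i], seed = seed),
      error = function(e) stop(sprintf("[%s] %s", key, conditionMessage(e)),
                               call. = FALSE)
    )
  }
  err <- matrix(NA_real_, nrow(combos), nrow(evals),
                dimnames = list(combos$label,
                                paste(evals$product_id, evals$measure, sep = "|")))
  for (ci in seq_len(nrow(combos))) {
    emb <- embeddings[[paste(combos$map_technique[ci], combos$data_mode[ci],
                             sep = "_")]]
    for (ei in seq_len(nrow(evals))) {
      g <- evaluation_grades(table, evals$product_id[ei], evals$measure[ei])
      sc <- scale_for_measure(evals$measure[ei], scales)
      model <- tryCatch(
        if (combos$regressor[ci] == "SVM") {
          do.call(fit_svm, c(list(emb, g), svm_params))
        } else {
          fit_quadratic(emb, g)
        },
        error = function(e) stop(sprintf("[%s] %s", combos$label[ci],
                                         conditionMessage(e)), call. = FALSE)
      )
      err[ci, ei] <- percentage_error(model, emb, g, sc)
    }
  }
  is_ol <- evals$measure == "overall_liking"
  results <- tibble::tibble(
    label = combos$label,
    map_technique = combos$map_technique,
    data_mode = combos$data_mode,
    regressor = combos$regressor,
    error_ol = rowMeans(err[, is_ol, drop = FALSE]),
    error_jar = rowMeans(err[, !is_ol, drop = FALSE])
  )
  results$error_avg <- (results$error_ol + results$error_jar) / 2
  ord <- lex_order(results$error_avg, results$label)
  results$rank <- match(seq_len(nrow(results)), ord)
  structure(list(results = results, errors = err, seed = seed),
            class = "lpl_benchmark")
}

#' @export
print.lpl_benchmark <- function(x, ...) {
  cat("<lpl_benchmark> 14 technique/data combinations, percentage error\n")
  res <- x$results[order(x$results$rank),
                   c("rank", "label", "error_ol", "error_jar", "error_avg")]
  print(as.data.frame(res), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Segment consumers by Ward hierarchical clustering
#'
#' Agglomerative clustering of the consumer vectors with Euclidean
#' distances and Ward's minimum-variance criterion. When `k` is not given
#' it is chosen to maximize the mean silhouette width over k = 2 ..
#' min(8, n-1), making the visual dendrogram cut reproducible.
#'
#' @param vectors An `lpl_vectors` object.
#' @param k Number of clusters; `NULL` to select by silhouette.
#' @return List of class `lpl_clustering`: `labels` (named integer vector),
#'   `tree` (the `hclust` dendrogram), `chosen_k`, `silhouette` (mean
#'   widths per candidate k, when selected).
#' @export
cluster_consumers <- function(vectors, k = NULL) {
  stopifnot(inherits(vectors, "lpl_vectors"))
  X <- vectors$matrix
  n <- nrow(X)
  if (n < 2L) stop("clustering needs at least 2 consumers", call. = FALSE)
  D <- stats::dist(X)
  if (max(D) < .Machine$double.eps) {
    warning("all consumer vectors are identical; returning a single cluster")
    return(structure(
      list(labels = stats::setNames(rep(1L, n), vectors$consumer_ids),
           tree = NULL, chosen_k = 1L, silhouette = NULL),
      class = "lpl_clustering"
    ))
  }
  tree <- stats::hclust(D, method = "ward.D2")
  sil <- NULL
  if (is.null(k)) {
    ks <- 2:min(8L, n - 1L)
    sil <- vapply(ks, function(kk) {
      labs <- stats::cutree(tree, k = kk)
      mean(cluster::silhouette(labs, D)[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    k <- ks[which.max(sil)]
  }
  labels <- stats::cutree(tree, k = k)
  names(labels) <- vectors$consumer_ids
  structure(list(labels = labels, tree = tree, chosen_k = as.integer(k),
                 silhouette = sil),
            class = "lpl_clustering")
}
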