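#' Color keys for landscape figures
#'
#' Hedonic landscapes use a diverging blue (dislike, 1) to red (like, 9)
#' ramp. JAR landscapes anchor five colors at the scale categories:
#' -2 dark blue (far too little), -1 blue, 0 green (just about right),
#' +1 yellow, +2 red (far too much), interpolated continuously in between.
#'
#' @param key `"hedonic"` or `"jar"`.
#' @return List with `limits`, `colors` (anchor colors low to high) and
#'   `ramp` (a function mapping values to hex colors).
#' @export
color_key <- function(key = c("hedonic", "jar")) {
  key <- match.arg(key)
  if (key == "hedonic") {
    limits <- c(1, 9)
    anchors <- c("#2166AC", "#F7F7F7", "#B2182B") # blue -> white -> red
  } else {
    limits <- c(-2, 2)
    anchors <- c("#08306B", "#2171B5", "#1A9641", "#FFD700", "#D7191C")
  }
  pal <- grDevices::colorRamp(anchors)
  ramp <- function(v) {
    t <- pmin(pmax((v - limits[1]) / diff(limits), 0), 1)
    rgb <- pal(t)
    grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  list(key = key, limits = limits, colors = anchors, ramp = ramp)
}

#' JAR category proportions for one product attribute
#'
#' The stacked-bar annotation of attribute landscapes: the proportion of
#' consumers giving each JAR category -2..+2 (ratings rounded to the
#' nearest category first, so simulated continuous panels bin cleanly).
#'
#' @param table An `lpl_table`.
#' @param product Product id.
#' @param attribute A JAR-scaled measure name.
#' @return Named numeric vector of 5 proportions (names `-2`..`2`) summing
#'   to 1.
#' @export
jar_bar <- function(table, product, attribute) {
  stopifnot(inherits(table, "lpl_table"))
  if (identical(attribute, "overall_liking")) {
    stop("jar_bar is defined for JAR attributes, not overall liking",
         call. = FALSE)
  }
  if (!attribute %in% table$measure) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  g <- evaluation_grades(table, product, attribute)
  cats <- -2:2
  binned <- pmin(pmax(round(g), -2), 2)
  counts <- vapply(cats, function(cc) sum(binned == cc), numeric(1))
  stats::setNames(counts / length(g), as.character(cats))
}

#' Compose a liking product landscape figure
#'
#' The composite map: the acceptance surface colored by the evaluation's
#' color key, made transparent where consumers are sparse (per-node alpha =
#' density / max density, so empty regions are white and the densest point
#' fully opaque), overlaid with density contours and the consumer points
#' colored by their own grades. Annotated with the mean grade (hedonic) or
#' the percentage of consumers finding the attribute just-about-right
#' (JAR), plus the surface's percentage error.
#'
#' @param surface An `lpl_surface`.
#' @param density An `lpl_density` on the same grid.
#' @param embedding The shared `lpl_embedding`.
#' @param key `"hedonic"` or `"jar"` (default chosen from the evaluation's
#'   measure).
#' @param title Optional figure title.
#' @return An object of class `lpl_figure`: the ggplot in `$plot` plus all
#'   numeric annotations.
#' @export
compose_lpl <- function(surface, density, embedding, key = NULL,
                        title = NULL) {
  stopifnot(inherits(surface, "lpl_surface"), inherits(density, "lpl_density"))
  if (!isTRUE(all.equal(surface$grid$x, density$grid$x)) ||
      !isTRUE(all.equal(surface$grid$y, density$grid$y))) {
    stop("surface and density must share one grid", call. = FALSE)
  }
  measure <- surface$evaluation_id[["measure"]]
  if (is.null(key)) {
    key <- if (identical(measure, "overall_liking")) "hedonic" else "jar"
  }
  ck <- color_key(key)
  alpha <- density$values / max(density$values)
  grid_df <- data.frame(
    x = rep(surface$grid$x, times = length(surface$grid$y)),
    y = rep(surface$grid$y, each = length(surface$grid$x)),
    f = as.vector(surface$values),
    dens = as.vector(density$values),
    alpha = as.vector(alpha)
  )
  pts <- data.frame(x = embedding$coords[, 1], y = embedding$coords[, 2],
                    grade = surface$grades)
  annotations <- list(
    percentage_error = surface$percentage_error,
    mean_grade = mean(surface$grades),
    jar_percentage = if (key == "jar") {
      100 * mean(pmin(pmax(round(surface$grades), -2), 2) == 0)
    } else NULL
  )
  ann_text <- if (key == "jar") {
    sprintf("JAR %.0f%% | err %.1f%%", annotations$jar_percentage,
            annotations$percentage_error)
  } else {
    sprintf("mean %.2f | err %.1f%%", annotations$mean_grade,
            annotations$percentage_error)
  }
  if (is.null(title)) {
    title <- paste(surface$evaluation_id, collapse = " / ")
  }
  plot <- ggplot2::ggplot(grid_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$f, alpha = .data$alpha)) +
    ggplot2::scale_fill_gradientn(colors = ck$colors, limits = ck$limits,
                                  oob = function(v, ...) pmin(pmax(v, ck$limits[1]), ck$limits[2]),
                                  name = measure) +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$dens),
                          breaks = density_contours(density, 5L),
                          color = "grey30", linewidth = 0.25) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        color = ck$ramp(pts$grade), size = 1.2) +
    ggplot2::labs(title = title, subtitle = ann_text, x = "dim 1", y = "dim 2") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  structure(
    list(plot = plot, surface = surface, density = density,
         embedding = embedding, color_key = ck, annotations = annotations,
         title = title),
    class = "lpl_figure"
  )
}

#' @export
print.lpl_figure <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

# shared scaffolding of the three analyses: one embedding + one density
analysis_context <- function(table, combo, seed) {
  parsed <- parse_combo(combo)
  embedding <- build_map(table, parsed$map_technique, parsed$data_mode,
                         seed = seed)
  grid <- make_grid(embedding)
  density <- estimate_density(embedding, grid)
  list(parsed = parsed, embedding = embedding, grid = grid, density = density)
}

one_landscape <- function(ctx, table, product, measure, scales, title) {
  g <- evaluation_grades(table, product, measure)
  sc <- scale_for_measure(measure, scales)
  model <- fit_acceptance(ctx$embedding, g, ctx$parsed$regressor)
  surf <- evaluate_surface(model, ctx$grid, ctx$embedding, g, sc,
                           evaluation_id = c(product = product,
                                             measure = measure))
  compose_lpl(surf, ctx$density, ctx$embedding, title = title)
}

#' Overall-liking analysis
#'
#' One landscape per product for overall liking, all on a single shared
#' consumer map and density, so consumer positions coincide across the
#' figures.
#'
#' @param table An `lpl_table`.
#' @param combo Technique/data/regressor label (default the recommended
#'   `"MDS_OLJAR_SVM"`).
#' @param seed Seed for the map construction.
#' @return An `lpl_analysis`: named list of `lpl_figure`s plus the shared
#'   `embedding` and `density`.
#' @export
overall_liking_analysis <- function(table, combo = "MDS_OLJAR_SVM",
                                    seed = 1L) {
  ctx <- analysis_context(table, combo, seed)
  scales <- attr(table, "scales")
  figs <- lapply(table_products(table), function(p) {
    one_landscape(ctx, table, p, "overall_liking", scales,
                  title = sprintf("%s: overall liking", p))
  })
  names(figs) <- table_products(table)
  structure(list(figures = figs, embedding = ctx$embedding,
                 density = ctx$density, combo = combo, kind = "overall_liking"),
            class = "lpl_analysis")
}

#' Product analysis
#'
#' For one product: a landscape for its overall liking and one per
#' attribute, on the shared map, so a disliked region can be read against
#' the attribute perceptions at the same location.
#'
#' @inheritParams overall_liking_analysis
#' @param product Product id to analyze.
#' @return An `lpl_analysis` with one figure per measure.
#' @export
product_analysis <- function(table, product, combo = "MDS_OLJAR_SVM",
                             seed = 1L) {
  if (!product %in% table$product_id) {
    stop("unknown product: ", product, call. = FALSE)
  }
  ctx <- analysis_context(table, combo, seed)
  scales <- attr(table, "scales")
  measures <- c("overall_liking", table_attributes(table))
  figs <- lapply(measures, function(m) {
    one_landscape(ctx, table, product, m, scales,
                  title = sprintf("%s: %s", product, m))
  })
  names(figs) <- measures
  structure(list(figures = figs, embedding = ctx$embedding,
                 density = ctx$density, combo = combo, kind = "product",
                 product = product),
            class = "lpl_analysis")
}

#' Attribute analysis
#'
#' For one JAR attribute: a landscape per product on the shared map, each
#' annotated with its JAR bar proportions.
#'
#' @inheritParams overall_liking_analysis
#' @param attribute JAR attribute to analyze.
#' @return An `lpl_analysis` with one figure per product; each figure
#'   carries `jar_bar` proportions in its annotations.
#' @export
attribute_analysis <- function(table, attribute, combo = "MDS_OLJAR_SVM",
                               seed = 1L) {
  if (!attribute %in% table_attributes(table)) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  ctx <- analysis_context(table, combo, seed)
  scales <- attr(table, "scales")
  figs <- lapply(table_products(table), function(p) {
    fig <- one_landscape(ctx, table, p, attribute, scales,
                         title = sprintf("%s: %s", p, attribute))
    fig$annotations$jar_bar <- jar_bar(table, p, attribute)
    fig
  })
  names(figs) <- table_products(table)
  structure(list(figures = figs, embedding = ctx$embedding,
                 density = ctx$density, combo = combo, kind = "attribute",
                 attribute = attribute),
            class = "lpl_analysis")
}

#' @export
print.lpl_analysis <- function(x, ...) {
  cat(sprintf("<lpl_analysis> %s analysis, %d figures, combo %s\n",
              x$kind, length(x$figures), x$combo))
  invisible(x)
}

#' Classic internal preference map figure
#'
#' Products as points, consumers as preference vectors (arrows from the
#' origin): a vector points toward the products its consumer graded
#' highest, and longer vectors belong to consumers who discriminate more
#' strongly among products.
#'
#' @param table An `lpl_table` (overall liking is used).
#' @param standardize Passed to [embed_ipm()].
#' @return List of class `lpl_figure` with the ggplot and the IPM
#'   embedding.
#' @export
ipm_plot <- function(table, standardize = FALSE) {
  emb <- embed_ipm(table, standardize = standardize)
  prod_df <- data.frame(x = emb$product_coords[, 1],
                        y = emb$product_coords[, 2],
                        product = rownames(emb$product_coords))
  cons_df <- data.frame(x = emb$coords[, 1], y = emb$coords[, 2],
                        segment = if (is.null(emb$segments)) "consumer"
                                  else emb$segments)
  plot <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = cons_df,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y,
                   color = .data$segment),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      alpha = 0.6, linewidth = 0.3
    ) +
    ggplot2::geom_point(data = prod_df,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = prod_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$product),
                       vjust = -1, size = 3) +
    ggplot2::labs(title = "Internal preference map",
                  x = sprintf("PC1 (%.1f%%)", 100 * emb$explained_variance[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * emb$explained_variance[2])) +
    ggplot2::theme_minimal()
  structure(list(plot = plot, embedding = emb, title = "IPM"),
            class = "lpl_figure")
}

#' Save the figures of an analysis
#'
#' @param analysis An `lpl_analysis`.
#' @param dir Output directory (created if needed).
#' @param format `"svg"` or `"png"`.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the written file paths.
#' @export
save_analysis <- function(analysis, dir, format = c("svg", "png"),
                          width = 6, height = 5, dpi = 150) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(analysis$figures), function(nm) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".", format))
    dev <- if (format == "svg") grDevices::svg else NULL
    ggplot2::ggsave(path, analysis$figures[[nm]]$plot, width = width,
                    height = height, dpi = dpi, device = dev)
    path
  }, character(1))
  invisible(paths)
}
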