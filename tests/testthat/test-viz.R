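test_that("JAR bars are proportions over the five categories", {
  df <- expand.grid(consumer_id = sprintf("c%d", 1:10), product_id = "p1",
                    measure = c("overall_liking", "sweetness"),
                    stringsAsFactors = FALSE)
  df$value <- ifelse(df$measure == "overall_liking", 5, 0)
  tab <- evaluation_table(df)
  expect_equal(unname(jar_bar(tab, "p1", "sweetness")), c(0, 0, 1, 0, 0))

  df$value[df$measure == "sweetness"] <- rep(c(-2, 2), 5)
  tab2 <- evaluation_table(df)
  expect_equal(unname(jar_bar(tab2, "p1", "sweetness")),
               c(0.5, 0, 0, 0, 0.5))
  expect_equal(sum(jar_bar(tab2, "p1", "sweetness")), 1)
  expect_error(jar_bar(tab2, "p1", "overall_liking"), "not overall liking")
  expect_error(jar_bar(tab2, "p1", "nope"), "unknown attribute")
})

test_that("at zero noise the women-only wine1 sweetness bar sits at -2", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0, seed = 1))
  women <- evaluation_table(tibble::as_tibble(tab)[tab$segment == "women", ])
  expect_equal(unname(jar_bar(women, "wine1", "sweetness")),
               c(1, 0, 0, 0, 0))
})

test_that("color keys honor the stated anchors", {
  jar <- color_key("jar")
  expect_equal(jar$ramp(0), "#1A9641")  # just-about-right is green
  expect_equal(jar$ramp(-2), "#08306B") # far too little: dark blue
  expect_equal(jar$ramp(2), "#D7191C")  # far too much: red
  hed <- color_key("hedonic")
  expect_equal(hed$ramp(1), "#2166AC")  # dislike: blue
  expect_equal(hed$ramp(9), "#B2182B")  # like: red
})

test_that("the composed landscape carries max-normalized alpha and exact annotations", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 23))
  emb <- embed_mds(to_vectors(tab, "OLJAR"), seed = 23)
  grid <- make_grid(emb, n = 40)
  dens <- estimate_density(emb, grid)
  g <- lpland:::evaluation_grades(tab, "wine4", "overall_liking")
  model <- fit_svm(emb, g)
  surf <- evaluate_surface(model, grid, emb, g, hedonic_scale(),
                           evaluation_id = c(product = "wine4",
                                             measure = "overall_liking"))
  fig <- compose_lpl(surf, dens, emb)
  alpha <- fig$plot$data$alpha
  expect_equal(max(alpha), 1)
  expect_equal(alpha, as.vector(dens$values) / max(dens$values))
  expect_equal(fig$annotations$mean_grade, mean(g), tolerance = 1e-9)
  expect_equal(fig$annotations$percentage_error,
               percentage_error(model, emb, g, hedonic_scale()),
               tolerance = 1e-9)
  expect_s3_class(fig$plot, "ggplot")
  # mismatched grids refuse to compose
  other <- estimate_density(emb, make_grid(emb, n = 30))
  expect_error(compose_lpl(surf, other, emb), "share one grid")
})

test_that("overall-liking analysis reproduces the designed preference pattern", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 29))
  ana <- overall_liking_analysis(tab, seed = 29)
  expect_length(ana$figures, 5L)
  expect_named(ana$figures, paste0("wine", 1:5))

  segs <- table_segments(tab)
  men <- segs == "men"
  surf_mean <- function(fig, mask) {
    mean(predict(fig$surface$model, ana$embedding$coords[mask, , drop = FALSE]))
  }
  # wine 1 splits the panel: men like it a lot, women dislike it
  w1 <- ana$figures[["wine1"]]
  expect_gte(surf_mean(w1, men) - surf_mean(w1, !men), 3)
  # wine 4 is liked by both segments, more by men
  w4 <- ana$figures[["wine4"]]
  expect_gt(surf_mean(w4, men), 6)
  expect_gt(surf_mean(w4, !men), 5)
  expect_gt(surf_mean(w4, men), surf_mean(w4, !men))
})

test_that("all figures of an analysis share one consumer map", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 31))
  ana <- product_analysis(tab, "wine3", seed = 31)
  expect_named(ana$figures, c("overall_liking", "acidity", "astringency",
                              "body", "fruitiness", "sweetness"),
               ignore.order = TRUE)
  coords <- lapply(ana$figures, function(f) f$embedding$coords)
  for (cc in coords) expect_identical(cc, ana$embedding$coords)
  expect_error(product_analysis(tab, "wine9"), "unknown product")
})

test_that("attribute analysis annotates JAR bars consistently", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 37))
  ana <- attribute_analysis(tab, "sweetness", seed = 37)
  expect_length(ana$figures, 5L)
  for (p in names(ana$figures)) {
    fig <- ana$figures[[p]]
    bar <- jar_bar(tab, p, "sweetness")
    expect_equal(fig$annotations$jar_bar, bar)
    expect_equal(fig$annotations$jar_percentage, 100 * bar[["0"]],
                 tolerance = 1e-9)
  }
  # designed perception: men find wine2 far too sweet (+2), women about +1;
  # the landscape over the men cluster must sit in the too-much region
  segs <- table_segments(tab)
  w2 <- ana$figures[["wine2"]]
  men_mean <- mean(predict(w2$surface$model,
                           ana$embedding$coords[segs == "men", , drop = FALSE]))
  expect_gt(men_mean, 1.5)
  expect_error(attribute_analysis(tab, "overall_liking"), "unknown attribute")
})

test_that("the classic IPM view points vectors at preferred products", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 41))
  fig <- ipm_plot(tab)
  emb <- fig$embedding
  # wine 4 has the highest pooled design mean (8.0): the panel-average
  # consumer-vector / product-point affinity (the biplot inner product that
  # reconstructs each centered grade) is largest for it
  affinity <- colMeans(emb$coords %*% t(emb$product_coords))
  expect_equal(names(which.max(affinity)), "wine4")

  # vector length grows with a consumer's grade variance
  df <- expand.grid(consumer_id = c(sprintf("pl%02d", 1:8), "flat", "sharp"),
                    product_id = paste0("p", 1:4), stringsAsFactors = FALSE)
  df$measure <- "overall_liking"
  base <- c(2, 4, 6, 8)
  withr::with_seed(2, noise <- round(runif(nrow(df), -1, 1)))
  df$value <- pmin(pmax(base[match(df$product_id, paste0("p", 1:4))] + noise,
                        1), 9)
  df$value[df$consumer_id == "flat"] <- 5 # no discrimination
  df$value[df$consumer_id == "sharp"] <- c(1, 3, 7, 9)[
    match(df$product_id[df$consumer_id == "sharp"], paste0("p", 1:4))]
  emb2 <- embed_ipm(evaluation_table(df))
  len <- sqrt(rowSums(emb2$coords^2))
  expect_gt(len[["sharp"]], len[["flat"]])

  # products graded identically by everyone coincide on the map
  df2 <- df
  df2$value[df2$product_id == "p2"] <- df2$value[df2$product_id == "p1"]
  emb3 <- embed_ipm(evaluation_table(df2))
  expect_equal(emb3$product_coords["p1", ], emb3$product_coords["p2", ],
               tolerance = 1e-10)
})

test_that("analysis figures save to disk", {
  tab <- simulate_panel(experiment1_spec(noise_sd = 0.5, seed = 43))
  ana <- overall_liking_analysis(tab, combo = "PCA_OLJAR_QUA", seed = 43)
  dir <- withr::local_tempdir()
  paths <- save_analysis(ana, dir, format = "png", width = 3, height = 2.5,
                         dpi = 60)
  expect_length(paths, 5L)
  expect_true(all(file.exists(paths)))
})
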