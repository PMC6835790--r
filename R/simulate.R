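#' Segment mean profiles of the two-segment wine panel
#'
#' The packaged design for the simulated experiment: two consumer segments
#' (women, men) with fixed mean ratings for 5 wines on overall liking
#' (9-point hedonic) and five JAR attributes (sweetness, acidity,
#' astringency, body, fruitiness; -2..+2).
#'
#' @return A tibble with columns `segment`, `product_id`, `measure`, `mean`
#'   (60 rows).
#' @export
experiment1_profiles <- function() {
  path <- system.file("extdata", "experiment1_profiles.csv", package = "lpland")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Define one simulated consumer segment
#'
#' @param segment_name Segment label.
#' @param n_consumers Number of consumers drawn from this profile.
#' @param means Tibble with columns `product_id`, `measure`, `mean`; every
#'   (product, measure) pair present, means within scale bounds.
#' @param scales Scale set from [default_scales()].
#' @return A `segment_profile` object.
#' @export
segment_profile <- function(segment_name, n_consumers, means,
                            scales = default_scales()) {
  means <- tibble::as_tibble(means)
  stopifnot(all(c("product_id", "measure", "mean") %in% names(means)),
            n_consumers >= 1L)
  products <- lex_sort(means$product_id)
  measures <- lex_sort(means$measure)
  if (nrow(means) != length(products) * length(measures)) {
    stop("segment profile must cover every (product, measure) pair exactly once",
         call. = FALSE)
  }
  for (i in seq_len(nrow(means))) {
    sc <- scale_for_measure(means$measure[[i]], scales)
    m <- means$mean[[i]]
    if (m < sc$min_value || m > sc$max_value) {
      stop(sprintf("profile mean %g for %s outside %s scale bounds",
                   m, means$measure[[i]], sc$name), call. = FALSE)
    }
  }
  structure(
    list(segment_name = segment_name, n_consumers = as.integer(n_consumers),
         means = means),
    class = "segment_profile"
  )
}

#' Define a panel simulation
#'
#' Consumers are drawn segment by segment: each consumer's rating for a
#' (product, measure) cell is the segment mean plus Gaussian noise, then
#' clipped to the scale bounds (if `clip`) and optionally rounded to the
#' nearest scale category (`round_to_scale`). Noise draws follow a fixed
#' order (consumer-major, then product, then measure, all lexicographic) so
#' a seed pins the exact table.
#'
#' @param profiles List of [segment_profile()] objects.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   scale units (>= 0).
#' @param seed Integer RNG seed.
#' @param clip Clip simulated values to the scale bounds (default `TRUE`).
#' @param round_to_scale Round values to the nearest integer scale category
#'   (default `FALSE`, so landscapes stay continuous).
#' @param scales Scale set from [default_scales()].
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(profiles, noise_sd = 0.5, seed = 1L,
                            clip = TRUE, round_to_scale = FALSE,
                            scales = default_scales()) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "segment_profile")),
            is.finite(noise_sd), noise_sd >= 0)
  total <- sum(vapply(profiles, function(p) p$n_consumers, integer(1)))
  if (total < 2L) stop("simulation needs at least 2 consumers", call. = FALSE)
  structure(
    list(profiles = profiles, noise_sd = noise_sd, seed = as.integer(seed),
         clip = isTRUE(clip), round_to_scale = isTRUE(round_to_scale),
         scales = scales),
    class = "simulation_spec"
  )
}

#' Simulation spec for the packaged two-segment experiment
#'
#' 50 women + 50 men, segment means from [experiment1_profiles()].
#'
#' @inheritParams simulation_spec
#' @return A `simulation_spec` with two 50-consumer profiles.
#' @export
experiment1_spec <- function(noise_sd = 0.5, seed = 1L, clip = TRUE,
                             round_to_scale = FALSE) {
  prof <- experiment1_profiles()
  mk <- function(seg) {
    segment_profile(seg, 50L, prof[prof$segment == seg,
                                   c("product_id", "measure", "mean")])
  }
  simulation_spec(list(mk("women"), mk("men")), noise_sd = noise_sd,
                  seed = seed, clip = clip, round_to_scale = round_to_scale)
}

#' Simulate a consumer panel
#'
#' @param spec A [simulation_spec()].
#' @return A validated [evaluation_table()] with segment labels.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  scales <- spec$scales
  blocks <- lapply(spec$profiles, function(prof) {
    means <- prof$means[lex_order(prof$means$product_id, prof$means$measure), ]
    ids <- sprintf("%s_%03d", prof$segment_name, seq_len(prof$n_consumers))
    cells <- means[rep(seq_len(nrow(means)), times = prof$n_consumers), ]
    cells$consumer_id <- rep(ids, each = nrow(means))
    cells$segment <- prof$segment_name
    cells
  })
  all_cells <- dplyr::bind_rows(blocks)
  values <- withr::with_seed(spec$seed, {
    all_cells$mean + stats::rnorm(nrow(all_cells), sd = spec$noise_sd)
  })
  lo <- vapply(all_cells$measure,
               function(m) scale_for_measure(m, scales)$min_value, integer(1))
  hi <- vapply(all_cells$measure,
               function(m) scale_for_measure(m, scales)$max_value, integer(1))
  if (spec$clip) values <- pmin(pmax(values, lo), hi)
  if (spec$round_to_scale) values <- round(values)
  all_cells$value <- values
  evaluation_table(
    all_cells[, c("consumer_id", "segment", "product_id", "measure", "value")],
    scales
  )
}

#' Segment-by-product mean ratings of a table
#'
#' Convenience summary used to compare a simulated panel against its design
#' profiles.
#'
#' @param table An `lpl_table` with a segment column.
#' @return Tibble with columns `segment`, `product_id`, `measure`, `mean`.
#' @export
segment_means <- function(table) {
  stopifnot(inherits(table, "lpl_table"), "segment" %in% names(table))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), segment, product_id, measure),
    mean = mean(value), .groups = "drop"
  )
  out[lex_order(out$segment, out$product_id, out$measure), ]
}
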