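#' Rating scale specification
#'
#' Describes one ordinal rating scale by its name and integer bounds. Two
#' scales are used throughout: the 9-point hedonic liking scale (1--9) and
#' the 5-point just-about-right (JAR) scale, coded signed so that 0 means
#' "just about right", -2 far too little and +2 far too much.
#'
#' @param name Scale name, `"hedonic"` or `"jar"`.
#' @param min_value,max_value Integer scale bounds.
#' @return An object of class `lpl_scale` with fields `name`, `min_value`,
#'   `max_value` and `n_points` (the count of scale categories).
#' @examples
#' scale_spec("hedonic", 1, 9)$n_points # 9
#' @export
scale_spec <- function(name, min_value, max_value) {
  stopifnot(is.character(name), length(name) == 1L)
  min_value <- as.integer(min_value)
  max_value <- as.integer(max_value)
  if (max_value <= min_value) {
    stop("scale_spec: max_value must exceed min_value", call. = FALSE)
  }
  structure(
    list(
      name = name,
      min_value = min_value,
      max_value = max_value,
      n_points = max_value - min_value + 1L
    ),
    class = "lpl_scale"
  )
}

#' @rdname scale_spec
#' @export
hedonic_scale <- function() scale_spec("hedonic", 1L, 9L)

#' @rdname scale_spec
#' @export
jar_scale <- function() scale_spec("jar", -2L, 2L)

#' @rdname scale_spec
#' @export
default_scales <- function() list(hedonic = hedonic_scale(), jar = jar_scale())

#' Resolve the scale that governs a measure
#'
#' `overall_liking` is rated on the hedonic scale; every other measure is an
#' attribute rated on the JAR scale.
#'
#' @param measure Measure name(s).
#' @param scales A list with elements `hedonic` and `jar` as from
#'   [default_scales()].
#' @return An `lpl_scale` (for a single measure) or list of them.
#' @export
scale_for_measure <- function(measure, scales = default_scales()) {
  pick <- function(m) if (identical(m, "overall_liking")) scales$hedonic else scales$jar
  if (length(measure) == 1L) pick(measure) else lapply(measure, pick)
}

# Locale-independent lexicographic sort used for every ordering contract.
lex_sort <- function(x) sort(unique(as.character(x)), method = "radix")

lex_order <- function(...) order(..., method = "radix")
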