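#' Construct and validate a consumer evaluation table
#'
#' The central data container: one row per consumer x product x measure, in a
#' complete block design. `value` must lie within the bounds of the scale
#' that governs its measure (hedonic for `overall_liking`, JAR otherwise).
#' Rows are sorted lexicographically by consumer, product, measure so every
#' downstream matrix is reproducible bit-for-bit.
#'
#' @param data A data frame with columns `consumer_id`, `product_id`,
#'   `measure`, `value` and optionally `segment`.
#' @param scales Scale set from [default_scales()].
#' @return A tibble of class `lpl_table` with a `scales` attribute.
#' @export
evaluation_table <- function(data, scales = default_scales()) {
  data <- tibble::as_tibble(as.data.frame(data)[, , drop = FALSE])
  attr(data, "out.attrs") <- NULL
  required <- c("consumer_id", "product_id", "measure", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("evaluation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$consumer_id <- as.character(data$consumer_id)
  data$product_id <- as.character(data$product_id)
  data$measure <- as.character(data$measure)
  data$value <- as.numeric(data$value)
  if (anyNA(data$value)) {
    stop("evaluation values contain missing or non-numeric entries",
         call. = FALSE)
  }

  # scale bounds, reported with the offending row
  for (i in seq_len(nrow(data))) {
    sc <- scale_for_measure(data$measure[[i]], scales)
    v <- data$value[[i]]
    if (v < sc$min_value || v > sc$max_value) {
      stop(sprintf(
        "scale violation in row %d: %s = %g outside %s scale [%d, %d]",
        i, data$measure[[i]], v, sc$name, sc$min_value, sc$max_value
      ), call. = FALSE)
    }
  }

  # complete block design: every (consumer, product, measure) exactly once
  key <- paste(data$consumer_id, data$product_id, data$measure, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    parts <- strsplit(key[which(dup)[1L]], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicated cell: consumer '%s', product '%s', measure '%s'",
                 parts[1L], parts[2L], parts[3L]), call. = FALSE)
  }
  consumers <- lex_sort(data$consumer_id)
  products <- lex_sort(data$product_id)
  measures <- lex_sort(data$measure)
  full <- expand.grid(
    measure = measures, product_id = products, consumer_id = consumers,
    stringsAsFactors = FALSE
  )
  full_key <- paste(full$consumer_id, full$product_id, full$measure, sep = "\r")
  absent <- setdiff(full_key, key)
  if (length(absent) > 0L) {
    parts <- strsplit(absent[[1L]], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "incomplete design: missing cell consumer '%s', product '%s', measure '%s' (%d missing in total)",
      parts[1L], parts[2L], parts[3L], length(absent)
    ), call. = FALSE)
  }

  if ("segment" %in% names(data)) {
    data$segment <- as.character(data$segment)
    seg_per_consumer <- tapply(data$segment, data$consumer_id,
                               function(s) length(unique(s)))
    if (any(seg_per_consumer > 1L)) {
      stop("a consumer is assigned to more than one segment", call. = FALSE)
    }
    data <- data[, c("consumer_id", "segment", "product_id", "measure", "value")]
  } else {
    data <- data[, c("consumer_id", "product_id", "measure", "value")]
  }
  data <- data[lex_order(data$consumer_id, data$product_id, data$measure), ]
  out <- structure(data, class = c("lpl_table", class(tibble::tibble())))
  attr(out, "scales") <- scales
  out
}

#' @export
print.lpl_table <- function(x, ...) {
  cat(sprintf(
    "<lpl_table> %d consumers x %d products x %d measures (%d cells)\n",
    length(unique(x$consumer_id)), length(unique(x$product_id)),
    length(unique(x$measure)), nrow(x)
  ))
  NextMethod()
}

#' Consumers, products, attributes of a table
#'
#' Attribute measures are every measure except `overall_liking`, i.e. the
#' JAR-scaled sensory attributes.
#'
#' @param table An `lpl_table`.
#' @return Character vector in lexicographic order.
#' @export
table_consumers <- function(table) lex_sort(table$consumer_id)

#' @rdname table_consumers
#' @export
table_products <- function(table) lex_sort(table$product_id)

#' @rdname table_consumers
#' @export
table_attributes <- function(table) {
  setdiff(lex_sort(table$measure), "overall_liking")
}

#' Per-consumer segment labels
#'
#' @param table An `lpl_table`.
#' @return Named character vector (one label per consumer, lexicographic
#'   consumer order), or `NULL` when the table has no segment column.
#' @export
table_segments <- function(table) {
  if (!"segment" %in% names(table)) return(NULL)
  first <- !duplicated(table$consumer_id)
  labs <- stats::setNames(table$segment[first], table$consumer_id[first])
  labs[lex_sort(table$consumer_id)]
}

#' Read a consumer evaluation CSV
#'
#' Accepts two dialects, auto-detected from the header. Long format has
#' columns `consumer_id`, `product_id`, `measure`, `value` (plus optional
#' `segment`). Wide format has `consumer_id` (plus optional `segment`) and
#' one `"product|measure"` column per evaluation.
#'
#' @param path CSV file path.
#' @param scales Scale set from [default_scales()].
#' @param jar_coding `"signed"` when JAR values are already coded -2..+2,
#'   `"onetofive"` when the file stores them as 1..5 (recentred by -3 on
#'   read).
#' @return A validated [evaluation_table()].
#' @export
read_evaluations <- function(path, scales = default_scales(),
                             jar_coding = c("signed", "onetofive")) {
  jar_coding <- match.arg(jar_coding)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  long_cols <- c("consumer_id", "product_id", "measure", "value")
  if (all(long_cols %in% names(raw))) {
    long <- raw
  } else if ("consumer_id" %in% names(raw) &&
             any(grepl("|", names(raw), fixed = TRUE))) {
    id_cols <- intersect(c("consumer_id", "segment"), names(raw))
    long <- tidyr::pivot_longer(
      raw, cols = -tidyr::all_of(id_cols),
      names_to = c("product_id", "measure"), names_sep = "\\|",
      values_to = "value"
    )
  } else {
    stop("unrecognized CSV dialect: need long columns ",
         "(consumer_id, product_id, measure, value) or wide 'product|measure' headers",
         call. = FALSE)
  }
  if (jar_coding == "onetofive") {
    is_jar <- long$measure != "overall_liking"
    long$value[is_jar] <- long$value[is_jar] - 3
  }
  evaluation_table(long, scales)
}

#' Write an evaluation table to CSV (long format)
#'
#' Round-trips with [read_evaluations()]: reading the written file yields an
#' identical table.
#'
#' @param table An `lpl_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluations <- function(table, path) {
  stopifnot(inherits(table, "lpl_table"))
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Flatten consumers into vectors under a data mode
#'
#' Each consumer becomes one row of an n x d matrix. Which evaluations enter
#' the vector is set by the data mode: `OL` uses only overall liking
#' (d = P), `JAR` only the attribute perceptions (d = P*A), `OLJAR` both
#' (d = P*(A+1)), for P products and A attributes. Columns are ordered
#' products-major, measures-minor, both lexicographic, so the matrix does
#' not depend on input row order.
#'
#' @param table An `lpl_table`.
#' @param data_mode One of `"OLJAR"`, `"OL"`, `"JAR"`.
#' @return An object of class `lpl_vectors`: fields `consumer_ids`,
#'   `matrix` (n x d, dimnames set), `data_mode`, `column_labels` (tibble of
#'   product/measure per column) and `segments` (or `NULL`).
#' @export
to_vectors <- function(table, data_mode = c("OLJAR", "OL", "JAR")) {
  data_mode <- match.arg(data_mode)
  stopifnot(inherits(table, "lpl_table"))
  measures <- switch(data_mode,
    OL = "overall_liking",
    JAR = table_attributes(table),
    OLJAR = lex_sort(table$measure)
  )
  if (length(measures) == 0L) {
    stop("data mode 'JAR' requires at least one attribute measure",
         call. = FALSE)
  }
  consumers <- table_consumers(table)
  products <- table_products(table)
  cols <- expand.grid(measure = measures, product_id = products,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  sub <- table[table$measure %in% measures, ]
  # validated complete design + lexicographic row sort => fill by column
  sub <- sub[lex_order(sub$consumer_id, sub$product_id, sub$measure), ]
  mat <- matrix(sub$value, nrow = length(consumers), ncol = nrow(cols),
                byrow = TRUE)
  dimnames(mat) <- list(consumers, paste(cols$product_id, cols$measure, sep = "|"))
  structure(
    list(
      consumer_ids = consumers,
      matrix = mat,
      data_mode = data_mode,
      column_labels = tibble::as_tibble(cols),
      segments = table_segments(table)
    ),
    class = "lpl_vectors"
  )
}

#' @export
print.lpl_vectors <- function(x, ...) {
  cat(sprintf("<lpl_vectors> %d consumers x %d dims, data mode %s\n",
              nrow(x$matrix), ncol(x$matrix), x$data_mode))
  invisible(x)
}
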