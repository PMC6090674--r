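#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange distinct group_by summarise ungroup
#' @importFrom stats setNames
NULL

# columns of an expression table that are not annotation columns
.annot_cols <- c("transcript_id", "rna_class")

#' Sample columns of an expression table
#'
#' @param x expression tibble (first column `transcript_id`, optional
#'   `rna_class`, remaining columns one per sample).
#' @return character vector of sample column names, in table order.
#' @export
sample_cols <- function(x) {
  setdiff(names(x), .annot_cols)
}

# numeric matrix of expression values, rownames = transcript ids
expr_values <- function(x) {
  m <- as.matrix(x[sample_cols(x)])
  rownames(m) <- x$transcript_id
  storage.mode(m) <- "double"
  m
}

#' Declare an expression table and its measurement scale
#'
#' Expression tables are plain tibbles with a `transcript_id` column, an
#' optional `rna_class` column and one numeric column per sample (time point,
#' optionally with a replicate tag such as `Day4_R1`). The measurement scale
#' (`raw_count`, `FPKM`, `RPM` or `log2p1`) is carried as an attribute and is
#' only changed by the normalization operations.
#'
#' @param x a data frame as described above.
#' @param scale one of `"raw_count"`, `"FPKM"`, `"RPM"`, `"log2p1"`.
#' @return the validated tibble with the `expr_scale` attribute set.
#' @export
expression_matrix <- function(x, scale = c("raw_count", "FPKM", "RPM", "log2p1")) {
  scale <- match.arg(scale)
  x <- as_tibble(x)
  if (!"transcript_id" %in% names(x)) {
    abort("expression table must have a 'transcript_id' column")
  }
  sc <- sample_cols(x)
  if (length(sc) == 0) abort("expression table has no sample columns")
  vals <- as.matrix(x[sc])
  if (anyNA(vals)) abort("expression table contains missing cells")
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (scale != "log2p1" && any(vals < 0)) {
    abort("expression values must be non-negative")
  }
  attr(x, "expr_scale") <- scale
  x
}

#' Measurement scale of an expression table
#' @param x expression tibble.
#' @return the `expr_scale` attribute, or `NULL` when undeclared.
#' @export
expr_scale <- function(x) attr(x, "expr_scale", exact = TRUE)

set_expr_scale <- function(x, scale) {
  attr(x, "expr_scale") <- scale
  x
}

# rebuild an expression tibble from a values matrix, keeping annotation cols
rebuild_expr <- function(template, values, scale) {
  out <- template
  out[sample_cols(template)] <- as_tibble(values)
  set_expr_scale(out, scale)
}

#' Parse day numbers out of sample labels
#'
#' Sample labels are expected to embed the sampling day as `Day<k>`, with an
#' optional replicate suffix (`Day4`, `Day10_R2`).
#'
#' @param labels character vector of sample labels.
#' @return integer vector of day numbers (NA when no day tag is present).
#' @export
sample_day <- function(labels) {
  m <- stringr::str_match(labels, "Day([0-9]+)")[, 2]
  as.integer(m)
}

# strip the replicate suffix from sample labels
sample_timepoint <- function(labels) {
  stringr::str_remove(labels, "_R[0-9]+$")
}

#' Average replicate columns of an expression table
#'
#' Columns sharing a time-point label (`Day10_R1`, `Day10_R2` -> `Day10`) are
#' collapsed to their mean; tables without replicate tags pass through
#' unchanged. Time-point order is preserved.
#'
#' @param x expression tibble.
#' @return expression tibble with one column per time point, same scale.
#' @export
average_replicates <- function(x) {
  sc <- sample_cols(x)
  tp <- sample_timepoint(sc)
  if (!anyDuplicated(tp)) return(x)
  vals <- expr_values(x)
  groups <- split(seq_along(sc), factor(tp, levels = unique(tp)))
  avg <- vapply(groups, function(j) rowMeans(vals[, j, drop = FALSE]),
                numeric(nrow(vals)))
  if (nrow(vals) == 1L) avg <- matrix(avg, nrow = 1, dimnames = list(NULL, names(groups)))
  out <- dplyr::bind_cols(x[intersect(.annot_cols, names(x))], as_tibble(avg))
  set_expr_scale(out, expr_scale(x))
}

# Pearson r between corresponding rows of two matrices (no p-value)
row_pearson <- function(a, b) {
  a <- sweep(a, 1, rowMeans(a))
  b <- sweep(b, 1, rowMeans(b))
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  unname(ifelse(den > 0, num / den, NA_real_))
}

# two-sided p-value for a Pearson correlation on n paired observations
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}
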