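#' Read miRNA-target predictions from one predictor
#'
#' The generic dialect is a headered TSV with columns `mirna_id`, `target_id`,
#' `target_class` and optional extra columns (scores, positions) which are
#' carried opaquely. Duplicate (miRNA, target) rows are collapsed.
#'
#' @param path prediction file.
#' @param predictor predictor name recorded on every edge.
#' @param dialect input dialect; only `"tsv"` is defined.
#' @return edge tibble: `mirna_id`, `target_id`, `target_class`, `predictors`.
#' @export
read_predictions <- function(path, predictor, dialect = "tsv") {
  if (!identical(dialect, "tsv")) abort(paste0("unknown dialect: ", dialect))
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    target_id = readr::col_character(),
    target_class = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE))
  need <- c("mirna_id", "target_id", "target_class")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("prediction file ", path,
                                 " lacks column(s): ", paste(miss, collapse = ", ")))
  bad <- which(is.na(x$mirna_id) | is.na(x$target_id) | is.na(x$target_class))
  if (length(bad)) abort(paste0("malformed prediction row(s) in ", path,
                                " at line(s): ",
                                paste(utils::head(bad + 1L, 5), collapse = ", ")))
  x |>
    distinct(.data$mirna_id, .data$target_id, .data$target_class) |>
    mutate(predictors = predictor)
}

#' Union-merge prediction tables from several predictors
#'
#' Set union of (miRNA, target) edges; the `predictors` column accumulates
#' comma-joined provenance. With `how = "intersect"`, only edges reported by
#' every input table are kept.
#'
#' @param tables list of edge tibbles (see [read_predictions()]).
#' @param how `"union"` (default, maximizes true-positive coverage) or
#'   `"intersect"`.
#' @return merged edge tibble sorted by (miRNA, target).
#' @export
union_merge <- function(tables, how = c("union", "intersect")) {
  how <- match.arg(how)
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) abort("union_merge() needs at least one table")
  n_tables <- length(tables)
  merged <- purrr::list_rbind(purrr::map(tables, as_tibble)) |>
    tidyr::separate_rows("predictors", sep = ",") |>
    group_by(.data$mirna_id, .data$target_id, .data$target_class) |>
    summarise(
      n_predictors = dplyr::n_distinct(.data$predictors),
      predictors = paste(sort(unique(.data$predictors)), collapse = ","),
      .groups = "drop"
    )
  if (how == "intersect" && n_tables > 1) {
    merged <- dplyr::filter(merged, .data$n_predictors == n_tables)
  }
  merged |>
    select(-"n_predictors") |>
    arrange(.data$mirna_id, .data$target_id)
}

#' Restrict a target table to expressed miRNAs and targets
#'
#' Drops edges whose miRNA or target failed the expression filters. The miRNA
#' universe of the restricted table (used as N in the shared-miRNA
#' hypergeometric test) is the set of expressed miRNAs retained in at least
#' one surviving edge.
#'
#' @param table edge tibble.
#' @param expressed_mirnas,expressed_targets character id sets from the
#'   expression module's filters.
#' @return restricted edge tibble.
#' @export
restrict_to_expressed <- function(table, expressed_mirnas, expressed_targets) {
  dplyr::filter(table,
                .data$mirna_id %in% expressed_mirnas,
                .data$target_id %in% expressed_targets)
}

#' miRNA universe of a target table
#' @param table edge tibble.
#' @return character vector of distinct miRNA ids.
#' @export
mirna_universe <- function(table) sort(unique(table$mirna_id))
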