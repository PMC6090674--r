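#' k-means clustering of ceRNA temporal profiles
#'
#' Profiles are z-scored per transcript across time points (shape-based
#' clustering; raw magnitudes would dominate otherwise) before Euclidean
#' k-means with `n_init` random restarts, keeping the best solution by total
#' within-cluster sum of squares. Constant rows have an undefined z-score and
#' are excluded with a warning.
#'
#' @param expr log2-scale expression tibble restricted to the transcripts of
#'   interest (typically the ceRNA-network RNA nodes), replicates averaged.
#' @param k number of clusters (default 6).
#' @param seed optional integer seed; the result is deterministic given it.
#' @param n_init number of k-means restarts.
#' @param standardize z-score rows first (set `FALSE` to cluster raw values).
#' @return object of class `cerna_clusters`: list with `assignment` (tibble
#'   `transcript_id`, `cluster`), `centroids` (k x time matrix), `inertia`,
#'   `k`, `n_init`, `seed`.
#' @export
cluster_cernas <- function(expr, k = 6, seed = NULL, n_init = 50,
                           standardize = TRUE) {
  vals <- expr_values(expr)
  if (nrow(vals) < k) abort("need at least k transcripts to form k clusters")
  if (standardize) {
    sds <- apply(vals, 1, stats::sd)
    constant <- sds == 0
    if (any(constant)) {
      warn(paste0(sum(constant),
                  " constant transcript(s) excluded from clustering ",
                  "(z-score undefined)"))
      vals <- vals[!constant, , drop = FALSE]
      if (nrow(vals) < k) abort("too few non-constant transcripts for k clusters")
    }
    vals <- t(scale(t(vals)))
  }
  if (!is.null(seed)) set.seed(seed)
  if (nrow(vals) == k) {
    # one transcript per cluster: the partition is forced
    fit <- list(cluster = seq_len(k), centers = vals, tot.withinss = 0)
  } else {
    fit <- stats::kmeans(vals, centers = k, nstart = n_init, iter.max = 100)
  }
  structure(
    list(
      assignment = tibble(transcript_id = rownames(vals),
                          cluster = unname(fit$cluster)),
      centroids = fit$centers,
      inertia = fit$tot.withinss,
      k = k, n_init = n_init, seed = seed %||% NA_integer_,
      standardized = standardize
    ),
    class = "cerna_clusters"
  )
}

#' @export
print.cerna_clusters <- function(x, ...) {
  cat("<cerna_clusters> k =", x$k, "over", nrow(x$assignment),
      "transcripts; inertia =", signif(x$inertia, 5), "\n")
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns with distance
#' `1 - Pearson(sample profiles)` and average linkage, plus the two-group cut
#' used to delimit the growth and senescence phases.
#'
#' @param expr log2-scale expression tibble (>= 4 samples).
#' @return object of class `sample_clustering`: list with `hclust`, `groups`
#'   (tibble `sample`, `group`), `distance`, `linkage`.
#' @export
cluster_samples <- function(expr) {
  vals <- expr_values(expr)
  if (ncol(vals) < 4) abort("sample clustering needs at least 4 samples")
  if (any(apply(vals, 2, stats::sd) == 0)) {
    abort("constant sample column: correlation distance undefined")
  }
  d <- stats::as.dist(1 - stats::cor(vals))
  hc <- stats::hclust(d, method = "average")
  cut <- stats::cutree(hc, k = 2)
  structure(
    list(
      hclust = hc,
      groups = tibble(sample = names(cut), group = unname(cut)),
      distance = "1 - Pearson", linkage = "average"
    ),
    class = "sample_clustering"
  )
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering>", attr(x$hclust, "method") %||% x$linkage,
      "linkage,", x$distance, "distance\n")
  print(split(x$groups$sample, x$groups$group))
  invisible(x)
}

#' Write a sample dendrogram in Newick format
#' @param x `sample_clustering` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram <- function(x, path) {
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

#' Fixed-day growth/senescence stage partition
#'
#' Growth stage: days up to 18; senescence stage: days from 20 on (the
#' two-phase split of the leaf lifespan). Labels whose day falls outside the
#' 4-30 sampling grid are still assigned by the day-18/20 threshold, with a
#' warning.
#'
#' @param labels sample labels carrying day numbers (`Day4` ... `Day30`).
#' @return named list with `growth` and `senescence` label vectors (class
#'   `stage_partition`), each ordered by day.
#' @export
default_stage_partition <- function(labels) {
  days <- sample_day(labels)
  if (anyNA(days)) abort("sample label(s) without a parseable day number")
  outside <- days < 4 | days > 30
  if (any(outside)) {
    warn(paste0("day(s) outside the 4-30 grid assigned by threshold: ",
                paste(labels[outside], collapse = ", ")))
  }
  ord <- order(days)
  labels <- labels[ord]; days <- days[ord]
  structure(
    list(growth = labels[days <= 18], senescence = labels[days >= 20]),
    class = c("stage_partition", "list")
  )
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model adjusted agreement between two cluster assignments of
#' the same items; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels over the same items (equal length).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must cover the same items")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
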