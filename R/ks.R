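KS_ALTERNATIVES <- c("match-down", "match-up", "two-sided")

new_group_split <- function(match_values, background_values,
                            match_label, background_label,
                            match_ids = NULL, background_ids = NULL,
                            tally = list()) {
  if (length(match_values) == 0L)
    stop("match group empty: no genes satisfy the match criterion")
  if (length(background_values) == 0L)
    stop("background group empty: every gene satisfies the match criterion")
  structure(list(match_values = as.numeric(match_values),
                 background_values = as.numeric(background_values),
                 match_label = match_label,
                 background_label = background_label,
                 match_ids = match_ids, background_ids = background_ids,
                 tally = tally),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat("group_split: ", x$match_label, " n=", length(x$match_values), " vs ",
      x$background_label, " n=", length(x$background_values), "\n", sep = "")
  invisible(x)
}

#' Split genes by seed-match status
#'
#' Partitions an annotated DE table into the match group (count >=
#' \code{min_count}) and background (count below it), carrying each group's
#' log2 fold changes into the ECDF comparison. The two groups are disjoint
#' and together cover the table.
#'
#' @param de DE results data.frame carrying a match-count column (see
#'   [annotate_de_results()]).
#' @param count_column Name of the count column; defaults to the column
#'   recorded by the last annotation when available.
#' @param min_count Minimum count to call a gene matched (default 1).
#' @return A \code{group_split} with \code{match_values},
#'   \code{background_values}, labels, and gene ids per group.
#' @export
split_by_match <- function(de, count_column = NULL, min_count = 1) {
  de <- validate_de(de)
  if (is.null(count_column))
    count_column <- attr(de, "annotation_tally")$column_name
  if (is.null(count_column) || !count_column %in% names(de))
    stop("count column '", count_column, "' not found in the DE table")
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("`min_count` must be >= 1")
  hit <- de[[count_column]] >= min_count
  new_group_split(de$log2FoldChange[hit], de$log2FoldChange[!hit],
                  match_label = paste0(count_column, " >= ", min_count),
                  background_label = "no seed match",
                  match_ids = de$gene_id[hit],
                  background_ids = de$gene_id[!hit])
}

#' Split genes by membership in a gene set
#'
#' Partitions a DE table into genes in a supplied set (e.g. predicted
#' miRNA targets) versus all other genes. Set ids absent from the table are
#' tallied, not an error.
#'
#' @param de DE results data.frame.
#' @param gene_set Character vector of gene ids, or path to a one-id-per-line
#'   text file (\code{#} comments and blank lines ignored).
#' @param set_label Display label for the set group.
#' @return A \code{group_split}; \code{tally$unmatched_set_ids} counts set
#'   ids not present in the table.
#' @export
split_by_gene_set <- function(de, gene_set, set_label = "gene set") {
  de <- validate_de(de)
  if (is.character(gene_set) && length(gene_set) == 1L &&
      file.exists(gene_set))
    gene_set <- read_gene_set(gene_set)
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L) stop("gene set is empty")
  hit <- de$gene_id %in% gene_set
  if (!any(hit))
    stop("no gene in the set is present in the DE table")
  new_group_split(de$log2FoldChange[hit], de$log2FoldChange[!hit],
                  match_label = set_label,
                  background_label = "background",
                  match_ids = de$gene_id[hit],
                  background_ids = de$gene_id[!hit],
                  tally = list(unmatched_set_ids =
                                 sum(!gene_set %in% de$gene_id)))
}

#' Read a gene set from a one-id-per-line text file
#'
#' @param path Text file, one gene id per line; blank lines and lines
#'   starting with \code{#} are skipped.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("gene set file '", path, "' contains no ids")
  unique(x)
}

#' Empirical cumulative distribution as a step table
#'
#' Right-continuous ECDF, F(x) = (number of values <= x) / n, tabulated at
#' the sorted unique values. This single routine backs both the KS statistic
#' and the ECDF plots.
#'
#' @param values Numeric vector with at least one finite value.
#' @return data.frame with columns \code{x} (sorted unique values) and
#'   \code{F} (cumulative fraction at \code{x}).
#' @examples
#' ecdf_table(c(1, 2, 2, 3)) # F(2) = 0.75
#' @export
ecdf_table <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values for the ECDF")
  x <- sort(unique(values))
  data.frame(x = x, F = cumsum(tabulate(match(sort(values), x))) /
               length(values))
}

# sup of the signed ECDF difference over the pooled unique points.
ks_d_stat <- function(x, y, alternative) {
  m <- length(x); n <- length(y)
  t <- sort(unique(c(x, y)))
  fx <- findInterval(t, sort(x)) / m
  fy <- findInterval(t, sort(y)) / n
  switch(alternative,
         "match-down" = max(fx - fy),
         "match-up" = max(fy - fx),
         "two-sided" = max(abs(fx - fy)))
}

# Exact null probability P(D >= d) by lattice-path counting: merge orders of
# the two samples are equally likely under the null (continuous data); a
# path vertex (i, j) has ECDF difference i/m - j/n, and the statistic is the
# sup over visited vertices. Counts paths that never reach the rejection
# band; valid only without cross-sample ties.
ks_exact_p <- function(d, m, n, alternative) {
  eps <- 1e-9
  if (d <= eps) return(1)
  inside <- function(diff) switch(alternative,
                                  "match-down" = diff < d - eps,
                                  "match-up" = -diff < d - eps,
                                  "two-sided" = abs(diff) < d - eps)
  u <- numeric(n + 1L)
  u[1L] <- 1
  for (j in seq_len(n)) u[j + 1L] <- if (inside(-j / n)) u[j] else 0
  for (i in seq_len(m)) {
    u[1L] <- if (inside(i / m)) u[1L] else 0
    for (j in seq_len(n)) {
      u[j + 1L] <- if (inside(i / m - j / n)) u[j + 1L] + u[j] else 0
    }
  }
  1 - u[n + 1L] / choose(m + n, m)
}

ks_asymptotic_p <- function(d, m, n, alternative) {
  lambda2 <- 2 * d^2 * m * n / (m + n)
  if (alternative == "two-sided") {
    k <- seq_len(100)
    p <- 2 * sum((-1)^(k - 1) * exp(-k^2 * lambda2))
  } else p <- exp(-lambda2)
  min(max(p, .Machine$double.xmin), 1)
}

#' One-sided two-sample Kolmogorov-Smirnov test on a group split
#'
#' Compares the ECDF of log2 fold changes for the match group against the
#' background. The default alternative, \code{"match-down"}, encodes the
#' seed-mediated off-target hypothesis: fold changes of matched genes are
#' stochastically smaller (distribution shifted left, downregulated), i.e.
#' the match-group ECDF lies above the background ECDF, and
#' \eqn{D = \sup_x [F_{match}(x) - F_{bg}(x)]}. \code{"match-up"} tests the
#' opposite shift (e.g. small activating RNA); \code{"two-sided"} uses the
#' absolute difference. The sup is evaluated at the pooled sorted unique
#' values, so ties are well-defined.
#'
#' P-values: the asymptotic one-sided bound
#' \eqn{p = \exp(-2 D^2 mn/(m+n))} by default (the Kolmogorov series for
#' two-sided); \code{p_method = "exact"} enumerates lattice paths for
#' \eqn{mn \le 10000} and tie-free data, falling back to the asymptotic
#' form (with a warning) otherwise.
#'
#' @param split A \code{group_split}.
#' @param alternative \code{"match-down"} (default), \code{"match-up"} or
#'   \code{"two-sided"}.
#' @param p_method \code{"asymptotic"} (default) or \code{"exact"}.
#' @param min_group_size Minimum values required in each group (default 3).
#' @return A \code{ks_result}: list with \code{d_stat}, \code{p_value},
#'   \code{alternative}, \code{n_match}, \code{n_background},
#'   \code{p_method} and the group labels.
#' @examples
#' s <- split_by_gene_set(
#'   data.frame(gene_id = paste0("g", 1:6),
#'              log2FoldChange = c(-1, -2, -3, 0, 1, 2)),
#'   c("g1", "g2", "g3"))
#' ks_ecdf_test(s)
#' @export
ks_ecdf_test <- function(split, alternative = "match-down",
                         p_method = "asymptotic", min_group_size = 3) {
  stopifnot(inherits(split, "group_split"))
  alternative <- match.arg(alternative, KS_ALTERNATIVES)
  p_method <- match.arg(p_method, c("asymptotic", "exact"))
  x <- split$match_values
  y <- split$background_values
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite fold changes present; filter the DE table first")
  m <- length(x); n <- length(y)
  if (m < min_group_size || n < min_group_size)
    stop("group sizes (", m, ", ", n, ") below the minimum of ",
         min_group_size)
  d <- ks_d_stat(x, y, alternative)
  used <- p_method
  if (p_method == "exact") {
    ties <- length(unique(c(x, y))) < m + n
    if (m * n > 10000 || ties) {
      warning("exact p-value unavailable (",
              if (ties) "ties present" else "m*n > 10000",
              "); using the asymptotic formula")
      used <- "asymptotic"
    }
  }
  p <- if (used == "exact") ks_exact_p(d, m, n, alternative)
       else ks_asymptotic_p(d, m, n, alternative)
  structure(list(d_stat = d, p_value = p, alternative = alternative,
                 n_match = m, n_background = n, p_method = used,
                 match_label = split$match_label,
                 background_label = split$background_label),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("Two-sample KS test (", x$alternative, ", ", x$p_method, " p)\n",
      "  ", x$match_label, " (n=", x$n_match, ") vs ", x$background_label,
      " (n=", x$n_background, ")\n",
      "  Dstat = ", format(x$d_stat, digits = 6),
      ", p-value = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a KS result as a one-row TSV
#'
#' @param x A \code{ks_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ks_result <- function(x, path) {
  stopifnot(inherits(x, "ks_result"))
  utils::write.table(
    data.frame(d_stat = x$d_stat, p_value = x$p_value,
               alternative = x$alternative, n_match = x$n_match,
               n_background = x$n_background, p_method = x$p_method),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full seed-mediated off-target test
#'
#' One-call pipeline: filter the DE table to the gene universe, count seed
#' matches per gene in the feature sequences, annotate the table, split by
#' match status, and run the one-sided KS comparison of log2 fold-change
#' ECDFs. All intermediate reports are retained in the return value.
#'
#' @param de DE results data.frame (see [read_de_results()]).
#' @param guide A \code{guide_sequence}, \code{seed_pattern}, or guide
#'   strand string.
#' @param features A \code{feature_seqs} object (see [get_feature_seqs()]).
#' @param seed Seed definition name, used when \code{guide} is not already a
#'   \code{seed_pattern}.
#' @param filters Named list passed to [filter_de_results()].
#' @param aggregation Gene-level aggregation policy, see
#'   [count_matches_per_gene()].
#' @param max_mismatch Substitutions tolerated per site (default 0).
#' @param min_count Minimum per-gene count to call a match (default 1).
#' @param alternative KS alternative, see [ks_ecdf_test()].
#' @param p_method KS p-value method.
#' @return An \code{offtarget_result}: list with \code{de} (filtered,
#'   annotated table), \code{split}, \code{ks}, \code{match_report},
#'   \code{filter_report}, \code{pattern}.
#' @export
run_offtarget_test <- function(de, guide, features, seed = "mer7m8",
                               filters = list(), aggregation = "max",
                               max_mismatch = 0, min_count = 1,
                               alternative = "match-down",
                               p_method = "asymptotic") {
  pattern <- if (inherits(guide, "seed_pattern")) guide
             else get_seed(guide, seed)
  de <- do.call(filter_de_results, c(list(de = de), filters))
  filter_report <- attr(de, "filter_report")
  report <- count_matches_per_gene(pattern, features,
                                   aggregation = aggregation,
                                   max_mismatch = max_mismatch)
  column_name <- paste0(pattern$guide_name, ".", pattern$definition$name)
  de <- annotate_de_results(de, report, column_name = column_name)
  split <- split_by_match(de, column_name, min_count = min_count)
  ks <- ks_ecdf_test(split, alternative = alternative, p_method = p_method)
  structure(list(de = de, split = split, ks = ks, match_report = report,
                 filter_report = filter_report, pattern = pattern),
            class = "offtarget_result")
}

#' @export
print.offtarget_result <- function(x, ...) {
  print(x$pattern)
  print(x$ks)
  invisible(x)
}
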