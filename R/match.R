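#' Count seed-target matches in sequences
#'
#' Counts the alignment start positions at which the DNA target pattern
#' matches each subject sequence with at most \code{max_mismatch}
#' substitutions. Overlapping occurrences are all counted; comparison is
#' case-insensitive; any position pairing a non-ACGT letter (e.g. \code{N})
#' counts as a mismatch. A pattern longer than the subject yields 0.
#'
#' @param pattern A \code{seed_pattern} (its \code{target_dna} is used) or a
#'   DNA string.
#' @param sequences A \code{DNAStringSet}, \code{feature_seqs} object, or
#'   character vector of DNA sequences.
#' @param max_mismatch Maximum substitutions tolerated per occurrence
#'   (default 0: exact seed matching). Indels are not supported.
#' @return Integer vector of counts, one per sequence.
#' @examples
#' count_seed_matches("CTCTATA", c("GGCTCTATAGG", "AAAA"))
#' @export
count_seed_matches <- function(pattern, sequences, max_mismatch = 0) {
  pat <- as_target_dna(pattern)
  if (nchar(pat) < 1L) stop("empty target pattern")
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L)
    stop("`max_mismatch` must be a non-negative integer")
  if (inherits(sequences, "feature_seqs")) sequences <- sequences$sequences
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  wide <- Biostrings::width(sequences) >= nchar(pat)
  counts <- integer(length(sequences))
  if (any(wide)) {
    if (max_mismatch == 0L) {
      counts[wide] <- Biostrings::vcountPattern(
        pat, sequences[wide], max.mismatch = 0, fixed = TRUE)
    } else {
      # with mismatches, matchPattern also reports alignments hanging off
      # the sequence ends; only fully contained alignments count
      mi <- Biostrings::vmatchPattern(pat, sequences[wide],
                                      max.mismatch = max_mismatch,
                                      fixed = TRUE)
      w <- Biostrings::width(sequences[wide])
      counts[wide] <- vapply(seq_along(mi), function(i) {
        ir <- mi[[i]]
        sum(IRanges::start(ir) >= 1L & IRanges::end(ir) <= w[i])
      }, integer(1))
    }
  }
  counts
}

MATCH_AGGREGATIONS <- c("max", "sum", "longest")

#' Count seed matches per gene across transcripts
#'
#' Counts target-pattern occurrences in every transcript's feature sequence
#' and collapses them to one count per gene. Byte-identical sequences within
#' a gene (shared UTRs across isoforms) are deduplicated first so they are
#' not double-counted. Aggregation policies: \code{"max"} (default) takes
#' the maximum over a gene's distinct sequences, \code{"sum"} adds them,
#' \code{"longest"} takes the count of the longest distinct sequence
#' (ties broken by transcript id order).
#'
#' @inheritParams count_seed_matches
#' @param features A \code{feature_seqs} object.
#' @param aggregation One of \code{"max"}, \code{"sum"}, \code{"longest"}.
#' @return A \code{match_report}: list with \code{genes} (data.frame:
#'   \code{gene_id}, \code{match_count}), \code{transcripts} (data.frame:
#'   \code{gene_id}, \code{transcript_id}, \code{width},
#'   \code{match_count}, \code{duplicate}), and \code{params}.
#' @export
count_matches_per_gene <- function(pattern, features, aggregation = "max",
                                   max_mismatch = 0) {
  stopifnot(inherits(features, "feature_seqs"))
  if (length(features$sequences) == 0L) stop("`features` is empty")
  if (!is.character(aggregation) || length(aggregation) != 1L ||
      !aggregation %in% MATCH_AGGREGATIONS)
    stop("unknown aggregation policy '", aggregation, "'; valid policies: ",
         paste(MATCH_AGGREGATIONS, collapse = ", "))
  info <- features$info
  counts <- count_seed_matches(pattern, features$sequences, max_mismatch)
  seq_chr <- as.character(features$sequences)
  dup <- logical(length(seq_chr))
  for (g in split(seq_len(nrow(info)), info$gene_id))
    dup[g] <- duplicated(seq_chr[g])
  tx <- data.frame(gene_id = info$gene_id,
                   transcript_id = info$transcript_id,
                   width = info$width,
                   match_count = counts,
                   duplicate = dup,
                   stringsAsFactors = FALSE)
  agg_one <- function(i) {
    i <- i[!tx$duplicate[i]]
    switch(aggregation,
           max = max(tx$match_count[i]),
           sum = sum(tx$match_count[i]),
           longest = tx$match_count[i][which.max(tx$width[i])])
  }
  by_gene <- split(seq_len(nrow(tx)), tx$gene_id)
  genes <- data.frame(gene_id = names(by_gene),
                      match_count = vapply(by_gene, agg_one, integer(1)),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  pat_def <- if (inherits(pattern, "seed_pattern"))
    pattern$definition$name else "custom"
  structure(list(genes = genes, transcripts = tx,
                 params = list(seed = pat_def,
                               target_dna = as_target_dna(pattern),
                               feature_type = features$feature_type,
                               aggregation = aggregation,
                               max_mismatch = max_mismatch)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report: ", nrow(x$genes), " genes (",
      sum(x$genes$match_count > 0), " with >=1 match) | target ",
      x$params$target_dna, " (", x$params$seed, ") in ",
      x$params$feature_type, ", aggregation=", x$params$aggregation,
      ", max_mismatch=", x$params$max_mismatch, "\n", sep = "")
  invisible(x)
}

#' Write a match report's tables as TSV
#'
#' @param x A \code{match_report}.
#' @param path Output path for the per-gene table; the per-transcript table
#'   goes to \code{<path>} with a \code{.transcripts.tsv} suffix when
#'   \code{transcripts = TRUE}.
#' @param transcripts Also write the per-transcript counts.
#' @return \code{path}, invisibly.
#' @export
write_match_report <- function(x, path, transcripts = FALSE) {
  stopifnot(inherits(x, "match_report"))
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (transcripts)
    utils::write.table(x$transcripts,
                       paste0(sub("\\.tsv$", "", path), ".transcripts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

DE_CANONICAL <- c(gene_id = "gene_id", log2_fold_change = "log2FoldChange",
                  base_mean = "baseMean", padj = "padj")

#' Read a differential-expression results table
#'
#' Reads a TSV/CSV of per-gene differential expression results (the
#' delimiter is sniffed from the header line unless given). DESeq2-style
#' column names (\code{log2FoldChange}, \code{baseMean}, \code{padj}) are
#' the defaults; any other naming is supplied through the \code{col_*}
#' arguments, so results from any differential expression method can be
#' used. Columns are renamed to the canonical DESeq2-style names; extra
#' columns pass through untouched.
#'
#' @param path Input table path.
#' @param col_gene,col_lfc,col_basemean,col_padj Column names in the file.
#' @param delim Field delimiter; \code{NULL} to sniff tab vs comma.
#' @return A data.frame with (at least) columns \code{gene_id},
#'   \code{log2FoldChange}, \code{baseMean}, \code{padj}, one row per gene.
#' @export
read_de_results <- function(path, col_gene = "gene_id",
                            col_lfc = "log2FoldChange",
                            col_basemean = "baseMean", col_padj = "padj",
                            delim = NULL) {
  if (!file.exists(path)) stop("DE results file not found: ", path)
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  de <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c(gene_id = col_gene, log2FoldChange = col_lfc,
              baseMean = col_basemean, padj = col_padj)
  miss <- wanted[!wanted %in% names(de)]
  if (length(miss))
    stop("DE table is missing column(s): ", paste(miss, collapse = ", "))
  names(de)[match(wanted, names(de))] <- names(wanted)
  validate_de(de)
}

validate_de <- function(de) {
  stopifnot(is.data.frame(de))
  need <- c("gene_id", "log2FoldChange")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene_id in DE table: ",
         de$gene_id[duplicated(de$gene_id)][1])
  de
}

#' Append per-gene seed match counts to a DE results table
#'
#' Joins a [count_matches_per_gene()] report onto the table by
#' \code{gene_id} (no ID translation is attempted). Row count, row order
#' and every pre-existing cell are preserved; genes absent from the report
#' get count 0. Tallies of genes missing from the report, and report genes
#' absent from the table, are attached as the \code{"annotation_tally"}
#' attribute.
#'
#' @param de DE results data.frame (see [read_de_results()]).
#' @param report A \code{match_report}.
#' @param column_name Name for the appended integer column (default: the
#'   guide/seed label from the report).
#' @param overwrite Allow replacing an existing column of that name.
#' @return \code{de} with the count column appended.
#' @export
annotate_de_results <- function(de, report, column_name = NULL,
                                overwrite = FALSE) {
  de <- validate_de(de)
  stopifnot(inherits(report, "match_report"))
  if (is.null(column_name))
    column_name <- paste0(report$params$seed, "_count")
  if (column_name %in% names(de) && !overwrite)
    stop("column '", column_name, "' already present in the DE table; ",
         "use overwrite = TRUE to replace it")
  idx <- match(de$gene_id, report$genes$gene_id)
  counts <- report$genes$match_count[idx]
  counts[is.na(counts)] <- 0L
  de[[column_name]] <- as.integer(counts)
  attr(de, "annotation_tally") <- list(
    genes_not_in_annotation = sum(is.na(idx)),
    annotation_genes_not_in_de = sum(!report$genes$gene_id %in% de$gene_id),
    column_name = column_name)
  de
}

#' Filter a DE results table to the gene universe for testing
#'
#' Applies permissive-by-default filters: drop rows with NA in the used
#' columns, then keep rows with \code{padj <= padj_cutoff},
#' \code{|log2FoldChange| >= fc_cutoff} and \code{baseMean >=
#' base_mean_min}. A per-rule removal tally is attached as the
#' \code{"filter_report"} attribute so the gene universe entering the ECDF
#' comparison is explicit and reproducible.
#'
#' @param de DE results data.frame.
#' @param padj_cutoff Keep rows with adjusted p-value at or below this
#'   (default 1: keep all).
#' @param fc_cutoff Keep rows with absolute log2 fold change at or above
#'   this, in log2 units (default 0: keep all).
#' @param base_mean_min Keep rows with mean normalized counts at or above
#'   this (default 0).
#' @param drop_na Drop rows with NA in any column an active filter uses, or
#'   in \code{log2FoldChange} (always needed downstream).
#' @return The filtered data.frame, attribute \code{"filter_report"} a
#'   data.frame of rows removed per rule.
#' @export
filter_de_results <- function(de, padj_cutoff = 1, fc_cutoff = 0,
                              base_mean_min = 0, drop_na = TRUE) {
  de <- validate_de(de)
  if (padj_cutoff < 0 || fc_cutoff < 0 || base_mean_min < 0)
    stop("filter thresholds must be non-negative")
  report <- data.frame(rule = character(), removed = integer(),
                       stringsAsFactors = FALSE)
  note <- function(rule, removed)
    rbind(report, data.frame(rule = rule, removed = removed))
  if (drop_na) {
    cols <- intersect(c("log2FoldChange", "padj", "baseMean"), names(de))
    na <- Reduce(`|`, lapply(cols, function(cl) is.na(de[[cl]])))
    report <- note("NA in used columns", sum(na))
    de <- de[!na, , drop = FALSE]
  }
  if ("padj" %in% names(de)) {
    bad <- !is.na(de$padj) & de$padj > padj_cutoff
    report <- note(paste0("padj > ", padj_cutoff), sum(bad))
    de <- de[!bad, , drop = FALSE]
  }
  bad <- !is.na(de$log2FoldChange) & abs(de$log2FoldChange) < fc_cutoff
  report <- note(paste0("|log2FC| < ", fc_cutoff), sum(bad))
  de <- de[!bad, , drop = FALSE]
  if ("baseMean" %in% names(de)) {
    bad <- !is.na(de$baseMean) & de$baseMean < base_mean_min
    report <- note(paste0("baseMean < ", base_mean_min), sum(bad))
    de <- de[!bad, , drop = FALSE]
  }
  rownames(de) <- NULL
  attr(de, "filter_report") <- report
  de
}

#' Write a DE results table
#'
#' @param de DE results data.frame.
#' @param path Output path; delimiter chosen from the extension
#'   (\code{.csv} comma, otherwise tab).
#' @return \code{path}, invisibly.
#' @export
write_de_results <- function(de, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(de, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
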