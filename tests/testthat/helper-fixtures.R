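# Small in-code fixture builders shared across test files.

write_fasta_plain <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  path
}

gtf_line <- function(chrom, feature, start, end, strand, gene, tx = NULL,
                     source = "test") {
  attrs <- sprintf('gene_id "%s";', gene)
  if (!is.null(tx)) attrs <- paste(attrs, sprintf('transcript_id "%s";', tx))
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, source, feature, start, end, strand, attrs)
}

# The canonical two-exon plus-strand fixture:
# exons 101-200 and 301-400, CDS 121-200 + 301-340, so the 3' UTR is
# 341-400 and the intron 201-300 (1-based inclusive).
two_exon_gtf <- function(path, strand = "+", utr_lines = FALSE) {
  lines <- c(
    gtf_line("chr1", "gene", 101L, 400L, strand, "gA"),
    gtf_line("chr1", "transcript", 101L, 400L, strand, "gA", "tA1"),
    gtf_line("chr1", "exon", 101L, 200L, strand, "gA", "tA1"),
    gtf_line("chr1", "exon", 301L, 400L, strand, "gA", "tA1"),
    gtf_line("chr1", "CDS", 121L, 200L, strand, "gA", "tA1"),
    gtf_line("chr1", "CDS", 301L, 340L, strand, "gA", "tA1"))
  if (utr_lines) {
    # 3' of the CDS in transcript orientation: right of it on "+",
    # left of it on "-"
    utr <- if (strand == "+") c(341L, 400L) else c(101L, 120L)
    lines <- c(lines, gtf_line("chr1", "three_prime_utr", utr[1], utr[2],
                               strand, "gA", "tA1"))
  }
  writeLines(lines, path)
  path
}

# In-memory feature_seqs object from parallel vectors, bypassing GTF/FASTA.
make_feature_seqs <- function(gene_id, transcript_id, seqs,
                              feature_type = "three_prime_utr") {
  ord <- order(gene_id, transcript_id)
  info <- data.frame(gene_id = gene_id[ord],
                     transcript_id = transcript_id[ord],
                     feature_type = feature_type,
                     n_intervals = 1L, width = nchar(seqs[ord]),
                     stringsAsFactors = FALSE)
  dss <- Biostrings::DNAStringSet(seqs[ord])
  names(dss) <- paste(info$gene_id, info$transcript_id, feature_type,
                      sep = "|")
  structure(list(sequences = dss, info = info, feature_type = feature_type,
                 skipped_transcripts = character(), n_clipped = 0L),
            class = "feature_seqs")
}

make_de <- function(gene_id, lfc, base_mean = 100, padj = 0.5) {
  data.frame(gene_id = gene_id, baseMean = base_mean,
             log2FoldChange = lfc, padj = padj, stringsAsFactors = FALSE)
}

make_split <- function(x, y) {
  sirnaseed::split_by_gene_set(
    make_de(paste0("g", seq_len(length(x) + length(y))), c(x, y)),
    paste0("g", seq_along(x)))
}
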