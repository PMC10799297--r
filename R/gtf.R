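#' Load gene models from a GTF annotation
#'
#' Parses a GTF file (plain or gzipped) and indexes exon, CDS, stop-codon and
#' any explicit UTR records per transcript. Coordinates are held as
#' \code{GRanges} (1-based inclusive, GTF's own convention); all downstream
#' interval arithmetic goes through GenomicRanges, so no manual coordinate
#' conversion ever happens in user code.
#'
#' Exon or CDS records lacking a \code{gene_id} or \code{transcript_id}
#' attribute are an error; exon records on strand \code{"."} are skipped
#' with a warning.
#'
#' @param gtf Path to a GTF file.
#' @return A \code{gene_model}: list with \code{genes} (data.frame:
#'   \code{gene_id}, \code{gene_name}, \code{chromosome}, \code{strand}),
#'   \code{transcripts} (data.frame: \code{transcript_id}, \code{gene_id},
#'   \code{chromosome}, \code{strand}), \code{exons}/\code{cds}/
#'   \code{stop_codon}/\code{utr3}/\code{utr5} (\code{GRangesList} split by
#'   transcript), and \code{source}.
#' @examples
#' \dontrun{
#' model <- read_gene_models("annotation.gtf")
#' }
#' @export
read_gene_models <- function(gtf) {
  if (!file.exists(gtf)) stop("GTF file not found: ", gtf)
  gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", gtf,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0L || !"type" %in% names(S4Vectors::mcols(gr)))
    stop("no gene records found in ", gtf)
  type <- as.character(gr$type)

  keep <- type %in% c("exon", "CDS", "stop_codon",
                      "three_prime_utr", "five_prime_utr", "3UTR", "5UTR")
  feat <- gr[keep]
  ftype <- type[keep]
  if (!any(ftype == "exon")) stop("no gene records (no exon features) in ", gtf)

  need <- ftype %in% c("exon", "CDS")
  gid <- as.character(feat$gene_id)
  tid <- as.character(feat$transcript_id)
  bad <- which(need & (is.na(gid) | gid == "" | is.na(tid) | tid == ""))
  if (length(bad))
    stop("GTF record ", bad[1], " (", ftype[bad[1]],
         ") lacks a gene_id/transcript_id attribute")

  nostrand <- which(ftype == "exon" &
                    as.character(GenomicRanges::strand(feat)) == "*")
  if (length(nostrand)) {
    warning(length(nostrand), " exon record(s) with unknown strand '.' skipped")
    drop <- rep(FALSE, length(feat))
    drop[nostrand] <- TRUE
    feat <- feat[!drop]; ftype <- ftype[!drop]
    gid <- gid[!drop]; tid <- tid[!drop]
  }

  split_by_tx <- function(what) {
    i <- which(ftype %in% what & !is.na(tid) & tid != "")
    g <- feat[i]
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = gid[i])
    GenomicRanges::sort(GenomicRanges::split(g, tid[i]), ignore.strand = TRUE)
  }
  exons <- split_by_tx("exon")
  cds <- split_by_tx("CDS")
  stopc <- split_by_tx("stop_codon")
  utr3 <- split_by_tx(c("three_prime_utr", "3UTR"))
  utr5 <- split_by_tx(c("five_prime_utr", "5UTR"))

  ex <- unlist(exons, use.names = FALSE)
  ex_tid <- rep(names(exons), lengths(exons))
  first <- !duplicated(ex_tid)
  transcripts <- data.frame(
    transcript_id = ex_tid[first],
    gene_id = ex$gene_id[first],
    chromosome = as.character(GenomeInfoDb::seqnames(ex))[first],
    strand = as.character(GenomicRanges::strand(ex))[first],
    stringsAsFactors = FALSE
  )
  transcripts <- transcripts[order(transcripts$gene_id,
                                   transcripts$transcript_id), ,
                             drop = FALSE]
  rownames(transcripts) <- NULL

  gfirst <- !duplicated(transcripts$gene_id)
  gene_name <- transcripts$gene_id
  if ("gene_name" %in% names(S4Vectors::mcols(gr))) {
    gn <- as.character(gr$gene_name)
    map <- gn[match(transcripts$gene_id[gfirst], as.character(gr$gene_id))]
    gene_name <- ifelse(is.na(map) | map == "",
                        transcripts$gene_id[gfirst], map)
  } else gene_name <- transcripts$gene_id[gfirst]
  genes <- data.frame(
    gene_id = transcripts$gene_id[gfirst],
    gene_name = gene_name,
    chromosome = transcripts$chromosome[gfirst],
    strand = transcripts$strand[gfirst],
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, stop_codon = stopc, utr3 = utr3, utr5 = utr5,
                 source = gtf),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model: ", nrow(x$genes), " genes, ", nrow(x$transcripts),
      " transcripts (", sum(lengths(x$exons)), " exons, ",
      sum(lengths(x$cds)), " CDS records)\n", sep = "")
  cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}
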