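FEATURE_TYPES <- c("three_prime_utr", "five_prime_utr", "cds", "exons",
                   "introns", "promoters")

#' Derive per-transcript genomic intervals for a feature type
#'
#' Computes, for every transcript in a [read_gene_models()] model, the
#' genomic intervals of the requested feature:
#' \itemize{
#'   \item \code{three_prime_utr} / \code{five_prime_utr}: explicit UTR
#'     records when the GTF carries them, otherwise inferred as the exonic
#'     region strictly 3' (resp. 5') of the CDS. When the GTF has
#'     stop-codon records, the CDS is first extended by its transcript's
#'     stop codon, so Ensembl-style annotations (CDS excludes the stop)
#'     and annotations that include it give the same UTR.
#'   \item \code{introns}: gaps between consecutive exons of a transcript.
#'   \item \code{promoters}: a window around the transcription start site,
#'     \code{upstream} nt before it and \code{downstream} nt from the TSS
#'     onward, in transcript orientation.
#'   \item \code{exons}, \code{cds}: the records themselves.
#' }
#' Transcripts lacking the feature (e.g. no annotated CDS, or a CDS running
#' to the transcript end) are omitted and tallied in the
#' \code{"skipped_transcripts"} attribute.
#'
#' @param model A \code{gene_model}.
#' @param feature One of \code{"three_prime_utr"}, \code{"five_prime_utr"},
#'   \code{"cds"}, \code{"exons"}, \code{"introns"}, \code{"promoters"}.
#' @param promoter_upstream,promoter_downstream Promoter window, nt relative
#'   to the TSS (defaults 2000 and 200).
#' @return A \code{GRangesList} named by transcript id, each element carrying
#'   a \code{gene_id} metadata column; attribute \code{skipped_transcripts}
#'   holds the ids of transcripts without the feature.
#' @export
feature_ranges <- function(model, feature = "three_prime_utr",
                           promoter_upstream = 2000,
                           promoter_downstream = 200) {
  stopifnot(inherits(model, "gene_model"))
  feature <- match.arg(feature, FEATURE_TYPES)
  out <- switch(feature,
    exons = model$exons,
    cds = model$cds,
    introns = derive_introns(model),
    promoters = derive_promoters(model, promoter_upstream,
                                 promoter_downstream),
    three_prime_utr = derive_utr(model, three_prime = TRUE),
    five_prime_utr = derive_utr(model, three_prime = FALSE)
  )
  out <- out[lengths(out) > 0L]
  skipped <- setdiff(model$transcripts$transcript_id, names(out))
  attr(out, "skipped_transcripts") <- skipped
  attr(out, "feature_type") <- feature
  out
}

derive_introns <- function(model) {
  span <- unlist(range(model$exons))
  gaps <- GenomicRanges::psetdiff(span, model$exons[names(span)])
  tx <- model$transcripts
  g <- unlist(gaps, use.names = FALSE)
  tid <- rep(names(gaps), lengths(gaps))
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    gene_id = tx$gene_id[match(tid, tx$transcript_id)])
  GenomicRanges::split(g, tid)
}

derive_promoters <- function(model, upstream, downstream) {
  if (upstream < 0 || downstream < 0)
    stop("promoter window sizes must be non-negative")
  span <- unlist(range(model$exons))
  prom <- GenomicRanges::promoters(span, upstream = upstream,
                                   downstream = downstream)
  tx <- model$transcripts
  S4Vectors::mcols(prom) <- S4Vectors::DataFrame(
    gene_id = tx$gene_id[match(names(prom), tx$transcript_id)])
  GenomicRanges::split(S4Vectors::unname(prom), names(prom))
}

# Exonic region strictly 3' (or 5') of the CDS, in transcript orientation.
derive_utr <- function(model, three_prime) {
  explicit <- if (three_prime) model$utr3 else model$utr5
  if (length(explicit) > 0L) return(explicit)
  if (length(model$cds) == 0L)
    stop("cannot derive ", if (three_prime) "3'" else "5'",
         " UTRs: the GTF has neither explicit UTR records nor CDS records ",
         "to infer them from")
  tids <- intersect(names(model$exons), names(model$cds))
  res <- lapply(tids, function(tid) {
    ex <- model$exons[[tid]]
    cds <- model$cds[[tid]]
    if (tid %in% names(model$stop_codon))
      cds <- GenomicRanges::reduce(c(GenomicRanges::granges(cds),
                                     GenomicRanges::granges(
                                       model$stop_codon[[tid]])))
    minus <- as.character(GenomicRanges::strand(ex)[1]) == "-"
    # "after the CDS" flips genomic direction on the minus strand
    utr <- if (three_prime != minus)  # + strand 3'UTR, - strand 5'UTR
      IRanges::restrict(GenomicRanges::granges(ex),
                        start = max(GenomicRanges::end(cds)) + 1L)
    else
      IRanges::restrict(GenomicRanges::granges(ex),
                        end = min(GenomicRanges::start(cds)) - 1L)
    if (length(utr) == 0L) return(NULL)
    S4Vectors::mcols(utr) <- S4Vectors::DataFrame(
      gene_id = rep(ex$gene_id[1], length(utr)))
    utr
  })
  names(res) <- tids
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(GenomicRanges::GRangesList())
  GenomicRanges::GRangesList(res)
}

# Map chromosome names in `wanted` onto names(genome), trying the
# "chr1" <-> "1" aliasing both ways.
alias_chromosomes <- function(wanted, available) {
  map <- stats::setNames(wanted, wanted)
  miss <- !wanted %in% available
  alt <- ifelse(grepl("^chr", wanted), sub("^chr", "", wanted),
                paste0("chr", wanted))
  map[miss] <- alt[miss]
  still <- !map %in% available
  if (any(still))
    stop("chromosome(s) absent from the genome FASTA even after chr-prefix ",
         "aliasing: ", paste(unique(wanted[still]), collapse = ", "))
  map
}

#' Extract transcript-oriented feature sequences from a genome
#'
#' Pulls the genomic slices of each transcript's feature intervals, splices
#' them in transcript 5'->3' order (minus-strand features are
#' reverse-complemented) and returns them with provenance. Intervals that
#' run off a chromosome end (promoters near contig edges) are clipped with
#' a warning and counted; chromosomes missing from the FASTA are an error
#' after a "chr" prefix aliasing pass.
#'
#' @param ranges A \code{GRangesList} from [feature_ranges()].
#' @param genome A \code{DNAStringSet} or path to a FASTA file (plain or
#'   gzipped).
#' @param feature_type Label stored with the records (taken from
#'   \code{ranges} when absent).
#' @return A \code{feature_seqs} object: list with \code{sequences}
#'   (\code{DNAStringSet} named \code{gene_id|transcript_id|feature_type},
#'   sorted by gene then transcript), \code{info} (data.frame with
#'   \code{gene_id}, \code{transcript_id}, \code{feature_type},
#'   \code{n_intervals}, \code{width}), \code{feature_type},
#'   \code{skipped_transcripts}, \code{n_clipped}.
#' @export
extract_feature_sequences <- function(ranges, genome, feature_type = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.null(feature_type))
    feature_type <- attr(ranges, "feature_type") %||% "feature"
  skipped <- attr(ranges, "skipped_transcripts") %||% character()
  if (length(ranges) == 0L) stop("no feature intervals to extract")

  flat <- unlist(ranges, use.names = FALSE)
  tid <- rep(names(ranges), lengths(ranges))
  chr_map <- alias_chromosomes(
    unique(as.character(GenomeInfoDb::seqnames(flat))), names(genome))

  n_clipped <- 0L
  seqs <- character(length(ranges))
  gene_ids <- character(length(ranges))
  n_iv <- integer(length(ranges))
  chrom_cache <- list()
  for (k in seq_along(ranges)) {
    gr <- ranges[[k]]
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    chr <- chr_map[[as.character(GenomeInfoDb::seqnames(gr)[1])]]
    subj <- genome[[chr]]
    st <- pmax(GenomicRanges::start(gr), 1L)
    en <- pmin(GenomicRanges::end(gr), length(subj))
    if (any(st != GenomicRanges::start(gr) | en != GenomicRanges::end(gr)))
      n_clipped <- n_clipped + sum(st != GenomicRanges::start(gr) |
                                   en != GenomicRanges::end(gr))
    ok <- st <= en
    st <- st[ok]; en <- en[ok]
    if (!length(st)) { seqs[k] <- ""; next }
    pieces <- Biostrings::extractAt(subj, IRanges::IRanges(st, en))
    s <- unlist(pieces)
    if (as.character(GenomicRanges::strand(gr)[1]) == "-")
      s <- Biostrings::reverseComplement(s)
    seqs[k] <- toupper(as.character(s))
    gene_ids[k] <- if ("gene_id" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$gene_id[1]) else NA_character_
    n_iv[k] <- length(st)
  }
  if (n_clipped > 0L)
    warning(n_clipped, " interval(s) clipped at chromosome boundaries")

  keep <- nzchar(seqs)
  info <- data.frame(gene_id = gene_ids[keep],
                     transcript_id = names(ranges)[keep],
                     feature_type = feature_type,
                     n_intervals = n_iv[keep],
                     width = nchar(seqs[keep]),
                     stringsAsFactors = FALSE)
  ord <- order(info$gene_id, info$transcript_id)
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  dss <- Biostrings::DNAStringSet(seqs[keep][ord])
  names(dss) <- paste(info$gene_id, info$transcript_id, info$feature_type,
                      sep = "|")
  structure(list(sequences = dss, info = info, feature_type = feature_type,
                 skipped_transcripts = union(skipped,
                                             names(ranges)[!keep]),
                 n_clipped = n_clipped),
            class = "feature_seqs")
}

#' One-call feature sequence extraction
#'
#' Convenience wrapper: [feature_ranges()] followed by
#' [extract_feature_sequences()].
#'
#' @inheritParams feature_ranges
#' @inheritParams extract_feature_sequences
#' @return A \code{feature_seqs} object.
#' @export
get_feature_seqs <- function(model, genome, feature = "three_prime_utr",
                             promoter_upstream = 2000,
                             promoter_downstream = 200) {
  rng <- feature_ranges(model, feature,
                        promoter_upstream = promoter_upstream,
                        promoter_downstream = promoter_downstream)
  extract_feature_sequences(rng, genome, feature_type = feature)
}

#' @export
print.feature_seqs <- function(x, ...) {
  cat("feature_seqs (", x$feature_type, "): ", length(x$sequences),
      " sequences over ", length(unique(x$info$gene_id)), " genes; ",
      length(x$skipped_transcripts), " transcript(s) lacked the feature\n",
      sep = "")
  invisible(x)
}

#' Write feature sequences as FASTA
#'
#' Record ids are \code{gene_id|transcript_id|feature_type}, so the file can
#' be fed back to [read_feature_fasta()] or any external tool.
#'
#' @param x A \code{feature_seqs} object.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_feature_fasta <- function(x, path) {
  stopifnot(inherits(x, "feature_seqs"))
  Biostrings::writeXStringSet(x$sequences, path)
  invisible(path)
}

#' Read feature sequences from a FASTA written by [write_feature_fasta()]
#'
#' @param path FASTA path with record ids \code{gene_id|transcript_id|type}.
#' @return A \code{feature_seqs} object.
#' @export
read_feature_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no sequences in ", path)
  parts <- strsplit(sub("\\s.*$", "", names(dss)), "|", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("FASTA record ids must look like gene_id|transcript_id|feature_type")
  info <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    transcript_id = vapply(parts, `[`, "", 2L),
    feature_type = vapply(parts, function(p)
      if (length(p) >= 3L) p[3L] else "feature", ""),
    n_intervals = NA_integer_,
    width = Biostrings::width(dss),
    stringsAsFactors = FALSE
  )
  ord <- order(info$gene_id, info$transcript_id)
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  dss <- dss[ord]
  names(dss) <- paste(info$gene_id, info$transcript_id, info$feature_type,
                      sep = "|")
  structure(list(sequences = dss, info = info,
                 feature_type = info$feature_type[1],
                 skipped_transcripts = character(), n_clipped = 0L),
            class = "feature_seqs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
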