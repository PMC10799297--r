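# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# sample() semantics are unsafe for length-1 vectors; index explicitly
pick_one <- function(x) x[sample.int(length(x), 1L)]
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random sequence guaranteed free of `pattern` (exact, overlapping).
rand_dna_without <- function(n, pattern) {
  repeat {
    s <- rand_dna(n)
    if (Biostrings::countPattern(pattern, Biostrings::DNAString(s)) == 0L)
      return(s)
  }
}

#' Configuration for the synthetic fixture generator
#'
#' Describes a toy study: a genome and annotation in which a chosen subset
#' of genes carries planted seed-target sites in its 3' UTR, and a matching
#' differential-expression table in which those genes' log2 fold changes
#' are shifted down by \code{delta}. Defaults describe the reference
#' validation scenario: 500 genes of which 100 carry sites, a planted shift
#' of 0.3 log2 units against noise of 0.5 log2 units.
#'
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @param n_genes Total genes.
#' @param n_match_genes Genes receiving at least one planted target site.
#' @param utr_length Length range (nt) of the 3' UTRs, sampled uniformly.
#' @param delta Planted shift, log2 units, subtracted from match genes'
#'   mean fold change (positive = downregulation).
#' @param sigma Fold-change noise s.d., log2 units; draws are
#'   Normal(-delta * is_match, sigma).
#' @param guide Guide strand sequence the sites are planted against.
#' @param seed_name Seed definition used to derive the planted pattern.
#' @param sites_per_match Range of planted sites per match gene.
#' @param minus_strand_prop Fraction of genes placed on the minus strand.
#' @param p_second_transcript Probability a gene gets a second transcript
#'   (an alternative-TSS isoform sharing the 3' UTR).
#' @param utr_lines Write explicit \code{three_prime_utr} GTF records (the
#'   CDS records always allow UTR inference, so both code paths can be
#'   compared on the same fixture).
#' @return A validated \code{fixture_config} list.
#' @export
fixture_config <- function(seed = 1, n_genes = 500, n_match_genes = 100,
                           utr_length = c(200, 500), delta = 0.3,
                           sigma = 0.5,
                           guide = "UUAUAGAGCAAGAACACUGUUUU",
                           seed_name = "mer7m8",
                           sites_per_match = c(1, 3),
                           minus_strand_prop = 0.5,
                           p_second_transcript = 0.3,
                           utr_lines = TRUE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_match_genes = as.integer(n_match_genes),
              utr_length = as.integer(utr_length), delta = delta,
              sigma = sigma, guide = guide, seed_name = seed_name,
              sites_per_match = as.integer(sites_per_match),
              minus_strand_prop = minus_strand_prop,
              p_second_transcript = p_second_transcript,
              utr_lines = isTRUE(utr_lines))
  if (cfg$n_genes < 2L || cfg$n_match_genes < 1L ||
      cfg$n_match_genes >= cfg$n_genes)
    stop("need 1 <= n_match_genes < n_genes")
  if (cfg$sigma <= 0) stop("sigma must be positive")
  pattern <- get_seed(guide_sequence(cfg$guide, "fixture"),
                      cfg$seed_name)$target_dna
  if (min(cfg$utr_length) < nchar(pattern))
    stop("UTR length range must be at least the target pattern length (",
         nchar(pattern), " nt)")
  cfg$target_dna <- pattern
  class(cfg) <- "fixture_config"
  cfg
}

# Fold changes and placeholder DESeq2-style columns for a fixed match
# status vector. padj comes from a two-sided z-approximation so filter
# code paths see realistic values; the KS analysis only uses the fold
# changes and the match split.
simulate_de_table <- function(is_match, delta, sigma,
                              gene_ids = sprintf("g%04d", seq_along(is_match))) {
  n <- length(is_match)
  lfc <- stats::rnorm(n, mean = -delta * as.numeric(is_match), sd = sigma)
  base_mean <- stats::rlnorm(n, meanlog = log(500), sdlog = 1)
  pvalue <- 2 * stats::pnorm(-abs(lfc) / sigma)
  data.frame(gene_id = gene_ids, baseMean = base_mean,
             log2FoldChange = lfc, pvalue = pvalue,
             padj = stats::p.adjust(pvalue, "BH"),
             stringsAsFactors = FALSE)
}

#' Generate a self-contained toy fixture set
#'
#' Writes a toy genome FASTA, a GTF annotation, a DESeq2-style DE results
#' table and a truth table into \code{outdir}. Every "match" gene's 3' UTR
#' carries at least one exact planted occurrence of the guide's seed target
#' pattern; every background gene's UTR is rejection-sampled to contain
#' none, so match status is recoverable exactly. Each gene has a two-exon
#' transcript (CDS split across the exons, UTR on the last exon) and,
#' with probability \code{p_second_transcript}, an alternative-TSS isoform
#' sharing the UTR. Fold changes of match genes are shifted by
#' \code{-delta}.
#'
#' @param config A [fixture_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the four file paths (\code{genome},
#'   \code{gtf}, \code{de}, \code{truth}), the \code{truth} data.frame, the
#'   \code{de} data.frame and the \code{config}.
#' @export
generate_fixture <- function(config = fixture_config(), outdir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pattern <- config$target_dna
  plen <- nchar(pattern)
  cds1_len <- 120L; intron_len <- 90L; cds2_len <- 60L

  with_seed(config$seed, {
    n <- config$n_genes
    is_match <- rep(FALSE, n)
    is_match[sample.int(n, config$n_match_genes)] <- TRUE
    minus <- stats::runif(n) < config$minus_strand_prop
    two_tx <- stats::runif(n) < config$p_second_transcript
    utr_len <- sample_range(config$utr_length[1], config$utr_length[2], n)

    gene_ids <- sprintf("g%04d", seq_len(n))
    chrom <- "chr1"
    cursor <- 0L
    genome_pieces <- character(n)
    gtf <- character(0)
    truth_sites <- character(n)
    n_sites <- integer(n)
    utr_seqs <- character(n)

    for (i in seq_len(n)) {
      ul <- utr_len[i]
      utr <- rand_dna_without(ul, pattern)
      sites <- integer(0)
      if (is_match[i]) {
        k <- sample_range(config$sites_per_match[1],
                          config$sites_per_match[2], 1L)
        avail <- seq_len(ul - plen + 1L)
        for (s in seq_len(k)) {
          if (!length(avail)) break
          pos <- pick_one(avail)
          substr(utr, pos, pos + plen - 1L) <- pattern
          sites <- c(sites, pos)
          avail <- setdiff(avail, seq(pos - plen + 1L, pos + plen - 1L))
        }
      }
      utr_seqs[i] <- utr
      n_sites[i] <- Biostrings::countPattern(pattern,
                                             Biostrings::DNAString(utr))
      truth_sites[i] <- paste(sort(sites), collapse = ";")

      tx_seq <- paste0(rand_dna(cds1_len), rand_dna(intron_len),
                       rand_dna(cds2_len), utr)
      frag <- if (minus[i])
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(tx_seq)))
      else tx_seq
      gap <- 100L + sample.int(100L, 1L)
      o <- cursor + gap
      L <- cds1_len + intron_len + cds2_len + ul
      strand <- if (minus[i]) "-" else "+"

      if (minus[i]) {
        ex2 <- c(o + 1L, o + ul + cds2_len)
        cds2 <- c(o + ul + 1L, o + ul + cds2_len)
        utr_iv <- c(o + 1L, o + ul)
        ex1 <- c(o + ul + cds2_len + intron_len + 1L, o + L)
        ex1b <- c(ex1[1], ex1[2] - 30L)  # alt TSS: 5' end trimmed 30 nt
      } else {
        ex1 <- c(o + 1L, o + cds1_len)
        ex2 <- c(o + cds1_len + intron_len + 1L, o + L)
        cds2 <- c(ex2[1], ex2[1] + cds2_len - 1L)
        utr_iv <- c(cds2[2] + 1L, o + L)
        ex1b <- c(ex1[1] + 30L, ex1[2])
      }
      gid <- gene_ids[i]
      attr1 <- function(tid) sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s";', gid, tid, gid)
      line <- function(feat, iv, tid) sprintf(
        "%s\tsirnaseed\t%s\t%d\t%d\t.\t%s\t.\t%s",
        chrom, feat, iv[1], iv[2], strand, attr1(tid))
      t1 <- paste0(gid, ".t1")
      g <- c(sprintf("%s\tsirnaseed\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
                     chrom, o + 1L, o + L, strand, gid, gid),
             line("transcript", c(o + 1L, o + L), t1),
             line("exon", ex1, t1), line("exon", ex2, t1),
             line("CDS", ex1, t1), line("CDS", cds2, t1),
             if (config$utr_lines) line("three_prime_utr", utr_iv, t1))
      if (two_tx[i]) {
        t2 <- paste0(gid, ".t2")
        tx2_span <- range(c(ex1b, ex2))
        g <- c(g, line("transcript", tx2_span, t2),
               line("exon", ex1b, t2), line("exon", ex2, t2),
               line("CDS", ex1b, t2), line("CDS", cds2, t2),
               if (config$utr_lines) line("three_prime_utr", utr_iv, t2))
      }
      gtf <- c(gtf, g)
      genome_pieces[i] <- paste0(rand_dna(gap), frag)
      cursor <- o + L
    }
    genome <- Biostrings::DNAStringSet(paste(genome_pieces, collapse = ""))
    names(genome) <- chrom

    de <- simulate_de_table(is_match, config$delta, config$sigma, gene_ids)
    truth <- data.frame(gene_id = gene_ids, is_match = is_match,
                        n_sites = n_sites, site_positions = truth_sites,
                        true_shift = -config$delta * as.numeric(is_match),
                        strand = ifelse(minus, "-", "+"),
                        utr_length = utr_len,
                        stringsAsFactors = FALSE)

    paths <- list(genome = file.path(outdir, "genome.fa"),
                  gtf = file.path(outdir, "annotation.gtf"),
                  de = file.path(outdir, "de_results.tsv"),
                  truth = file.path(outdir, "truth.tsv"))
    Biostrings::writeXStringSet(genome, paths$genome)
    writeLines(gtf, paths$gtf)
    utils::write.table(de, paths$de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(paths = paths, truth = truth, de = de, config = config))
  })
}

#' Monte-Carlo power and type-I error of the off-target KS test
#'
#' Simulates the fold-change layer of the fixture (match statuses fixed,
#' draws Normal(-delta * is_match, sigma)) and records how often the
#' one-sided KS test rejects at level \code{alpha}, for every combination
#' of \code{delta} and \code{sigma}. \code{delta = 0} rows estimate the
#' type-I error.
#'
#' @param delta Vector of planted shifts (log2 units).
#' @param sigma Vector of noise s.d. values (log2 units).
#' @param n_match,n_background Group sizes.
#' @param n_rep Replicates per grid cell.
#' @param alpha Rejection level.
#' @param alternative KS alternative (default \code{"match-down"}).
#' @param seed RNG seed.
#' @return data.frame with one row per (\code{delta}, \code{sigma}) cell:
#'   \code{rejection_rate} and its Monte-Carlo standard error \code{mc_se}.
#' @export
simulate_power <- function(delta = c(0, 0.3), sigma = 0.5, n_match = 100,
                           n_background = 400, n_rep = 200, alpha = 0.05,
                           alternative = "match-down", seed = 1) {
  stopifnot(n_rep >= 1, alpha > 0, alpha < 1, all(sigma > 0))
  grid <- expand.grid(delta = delta, sigma = sigma,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    grid$rejection_rate <- vapply(seq_len(nrow(grid)), function(r) {
      d <- grid$delta[r]; s <- grid$sigma[r]
      rej <- vapply(seq_len(n_rep), function(k) {
        x <- stats::rnorm(n_match, -d, s)
        y <- stats::rnorm(n_background, 0, s)
        dk <- ks_d_stat(x, y, alternative)
        ks_asymptotic_p(dk, n_match, n_background, alternative) < alpha
      }, logical(1))
      mean(rej)
    }, numeric(1))
  })
  grid$n_match <- n_match
  grid$n_background <- n_background
  grid$n_rep <- n_rep
  grid$mc_se <- sqrt(grid$rejection_rate * (1 - grid$rejection_rate) / n_rep)
  grid
}
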