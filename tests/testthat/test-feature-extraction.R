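make_two_exon_fixture <- function(strand = "+", utr_lines = FALSE,
                                  seed = 11) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  chrom <- rand_dna_chr(600)
  fa <- write_fasta_plain(c(chr1 = chrom), file.path(dir, "genome.fa"))
  gtf <- two_exon_gtf(file.path(dir, "fix.gtf"), strand = strand,
                      utr_lines = utr_lines)
  list(fa = fa, gtf = gtf, chrom = chrom)
}

test_that("GTF round-trips into an indexed gene model", {
  fx <- make_two_exon_fixture()
  model <- read_gene_models(fx$gtf)
  expect_equal(nrow(model$genes), 1L)
  expect_equal(nrow(model$transcripts), 1L)
  expect_equal(lengths(model$exons)[["tA1"]], 2L)
  expect_equal(lengths(model$cds)[["tA1"]], 2L)
})

test_that("3' UTR is inferred as the exonic region 3' of the CDS", {
  fx <- make_two_exon_fixture("+")
  model <- read_gene_models(fx$gtf)
  utr <- feature_ranges(model, "three_prime_utr")
  expect_equal(names(utr), "tA1")
  expect_equal(GenomicRanges::start(utr[["tA1"]]), 341L)
  expect_equal(GenomicRanges::end(utr[["tA1"]]), 400L)
})

test_that("explicit three_prime_utr records agree with CDS-based inference", {
  for (strand in c("+", "-")) {
    fx <- make_two_exon_fixture(strand, utr_lines = TRUE)
    model <- read_gene_models(fx$gtf)
    explicit <- feature_ranges(model, "three_prime_utr")
    model$utr3 <- GenomicRanges::GRangesList()  # force inference path
    inferred <- feature_ranges(model, "three_prime_utr")
    expect_equal(as.data.frame(IRanges::ranges(explicit[["tA1"]])),
                 as.data.frame(IRanges::ranges(inferred[["tA1"]])))
    s1 <- extract_feature_sequences(explicit, fx$fa)
    s2 <- extract_feature_sequences(inferred, fx$fa)
    expect_equal(as.character(s1$sequences), as.character(s2$sequences))
  }
})

test_that("introns are the gaps between consecutive exons", {
  fx <- make_two_exon_fixture()
  model <- read_gene_models(fx$gtf)
  introns <- feature_ranges(model, "introns")
  expect_equal(GenomicRanges::start(introns[["tA1"]]), 201L)
  expect_equal(GenomicRanges::end(introns[["tA1"]]), 300L)
})

test_that("minus-strand 3' UTR sits 5' of the CDS in genomic coordinates", {
  fx <- make_two_exon_fixture("-")
  model <- read_gene_models(fx$gtf)
  utr <- feature_ranges(model, "three_prime_utr")
  # on the minus strand the transcript reads right-to-left: UTR 101-120
  expect_equal(GenomicRanges::start(utr[["tA1"]]), 101L)
  expect_equal(GenomicRanges::end(utr[["tA1"]]), 120L)
  fs <- extract_feature_sequences(utr, fx$fa)
  expect_equal(as.character(fs$sequences)[[1]],
               revcomp_chr(substr(fx$chrom, 101, 120)))
})

test_that("promoter windows follow transcript orientation", {
  dir <- withr::local_tempdir()
  set.seed(12)
  chrom <- rand_dna_chr(700)
  fa <- write_fasta_plain(c(chr1 = chrom), file.path(dir, "g.fa"))
  gtf <- file.path(dir, "m.gtf")
  writeLines(c(gtf_line("chr1", "exon", 401L, 500L, "-", "gM", "tM1")),
             gtf)
  model <- read_gene_models(gtf)
  prom <- feature_ranges(model, "promoters", promoter_upstream = 10,
                         promoter_downstream = 5)
  # minus-strand TSS at 500: 5 downstream bases 496..500, 10 upstream 501..510
  expect_equal(GenomicRanges::start(prom[["tM1"]]), 496L)
  expect_equal(GenomicRanges::end(prom[["tM1"]]), 510L)
  fs <- extract_feature_sequences(prom, fa)
  expect_equal(as.character(fs$sequences)[[1]],
               revcomp_chr(substr(chrom, 496, 510)))
})

test_that("single-interval minus-strand extraction reverse-complements", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6), strand = "-",
                               gene_id = "g1")
  rng <- GenomicRanges::GRangesList(t1 = gr)
  fs <- extract_feature_sequences(rng,
                                  Biostrings::DNAStringSet(c(chr1 = "AAACCC")))
  expect_equal(as.character(fs$sequences)[[1]], "GGGTTT")
})

test_that("spliced extraction matches the brute-force oracle on both strands", {
  set.seed(13)
  for (i in 1:25) {
    chrom <- rand_dna_chr(400)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    n_ex <- sample(1:4, 1)
    bounds <- sort(sample(seq_len(398), 2 * n_ex))
    starts <- bounds[seq(1, 2 * n_ex, 2)] ; ends <- bounds[seq(2, 2 * n_ex, 2)]
    strand <- sample(c("+", "-"), 1)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                                 strand = strand, gene_id = "g1")
    fs <- extract_feature_sequences(GenomicRanges::GRangesList(tx = gr),
                                    genome)
    got <- as.character(fs$sequences)[[1]]
    expect_equal(got, brute_extract(chrom, starts, ends, strand))
    # length conservation
    expect_equal(nchar(got), sum(ends - starts + 1L))
    # strand involution: minus extraction == revcomp of plus extraction
    expect_equal(brute_extract(chrom, starts, ends, "-"),
                 revcomp_chr(brute_extract(chrom, starts, ends, "+")))
  }
})

test_that("chromosome aliasing maps chr-prefixed and bare names", {
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(2, 4), strand = "+",
                               gene_id = "g1")
  fs <- extract_feature_sequences(GenomicRanges::GRangesList(t1 = gr),
                                  Biostrings::DNAStringSet(c(chr1 = "ACGTAC")))
  expect_equal(as.character(fs$sequences)[[1]], "CGT")
  gr2 <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 3), strand = "+",
                                gene_id = "g1")
  expect_error(
    extract_feature_sequences(GenomicRanges::GRangesList(t1 = gr2),
                              Biostrings::DNAStringSet(c(chr1 = "ACGTAC"))),
    "absent from the genome")
})

test_that("intervals beyond the chromosome end are clipped with a warning", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4, 12), strand = "+",
                               gene_id = "g1")
  expect_warning(
    fs <- extract_feature_sequences(GenomicRanges::GRangesList(t1 = gr),
                                    Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))),
    "clipped")
  expect_equal(as.character(fs$sequences)[[1]], "TACGT")
  expect_equal(fs$n_clipped, 1L)
})

test_that("degenerate GTF inputs produce informative errors", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.gtf")
  writeLines(character(0), empty)
  expect_error(read_gene_models(empty), "parse|no gene records")
  exon_only <- file.path(dir, "exononly.gtf")
  writeLines(gtf_line("chr1", "exon", 1L, 50L, "+", "g1", "t1"), exon_only)
  model <- read_gene_models(exon_only)
  expect_error(feature_ranges(model, "three_prime_utr"),
               "neither explicit UTR records nor CDS")
  nostrand <- file.path(dir, "nostrand.gtf")
  writeLines(c(gtf_line("chr1", "exon", 1L, 50L, "+", "g1", "t1"),
               gtf_line("chr1", "exon", 60L, 90L, ".", "g2", "t2")),
             nostrand)
  expect_warning(model <- read_gene_models(nostrand), "unknown strand")
  expect_equal(nrow(model$transcripts), 1L)
  expect_error(read_gene_models(file.path(dir, "missing.gtf")), "not found")
})

test_that("record order is sorted by gene and transcript, not GTF order", {
  dir <- withr::local_tempdir()
  set.seed(14)
  chrom <- rand_dna_chr(300)
  fa <- write_fasta_plain(c(chr1 = chrom), file.path(dir, "g.fa"))
  lines <- c(gtf_line("chr1", "exon", 200L, 250L, "+", "gB", "tB1"),
             gtf_line("chr1", "exon", 10L, 60L, "+", "gA", "tA1"))
  g1 <- file.path(dir, "a.gtf"); writeLines(lines, g1)
  g2 <- file.path(dir, "b.gtf"); writeLines(rev(lines), g2)
  fs1 <- get_feature_seqs(read_gene_models(g1), fa, "exons")
  fs2 <- get_feature_seqs(read_gene_models(g2), fa, "exons")
  expect_identical(names(fs1$sequences), names(fs2$sequences))
  expect_identical(fs1$info$gene_id, c("gA", "gB"))
})

test_that("stop-codon records extend the CDS before UTR inference", {
  dir <- withr::local_tempdir()
  set.seed(15)
  chrom <- rand_dna_chr(600)
  fa <- write_fasta_plain(c(chr1 = chrom), file.path(dir, "g.fa"))
  # Ensembl-style: CDS excludes the stop codon 341-343
  gtf <- file.path(dir, "s.gtf")
  writeLines(c(gtf_line("chr1", "exon", 101L, 200L, "+", "gA", "tA1"),
               gtf_line("chr1", "exon", 301L, 400L, "+", "gA", "tA1"),
               gtf_line("chr1", "CDS", 121L, 200L, "+", "gA", "tA1"),
               gtf_line("chr1", "CDS", 301L, 340L, "+", "gA", "tA1"),
               gtf_line("chr1", "stop_codon", 341L, 343L, "+", "gA", "tA1")),
             gtf)
  model <- read_gene_models(gtf)
  utr <- feature_ranges(model, "three_prime_utr")
  expect_equal(GenomicRanges::start(utr[["tA1"]]), 344L)
  expect_equal(GenomicRanges::end(utr[["tA1"]]), 400L)
})

test_that("feature FASTA output round-trips through read_feature_fasta", {
  fx <- make_two_exon_fixture()
  fs <- get_feature_seqs(read_gene_models(fx$gtf), fx$fa, "three_prime_utr")
  out <- withr::local_tempfile(fileext = ".fa")
  write_feature_fasta(fs, out)
  back <- read_feature_fasta(out)
  expect_equal(as.character(back$sequences), as.character(fs$sequences))
  expect_equal(back$info$gene_id, fs$info$gene_id)
})
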