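test_that("splitting by match count partitions the gene universe", {
  de <- make_de(paste0("g", 1:4), c(-1, -2, -3, 1))
  de$cnt <- c(0L, 1L, 2L, 0L)
  s <- split_by_match(de, "cnt")
  expect_setequal(s$match_values, c(-2, -3))
  expect_setequal(s$background_values, c(-1, 1))
  expect_setequal(c(s$match_ids, s$background_ids), de$gene_id)
  s2 <- split_by_match(de, "cnt", min_count = 2)
  expect_equal(s2$match_values, -3)
  de$cnt <- 0L
  expect_error(split_by_match(de, "cnt"), "match group empty")
  expect_error(split_by_match(de, "nope"), "not found")
  expect_error(split_by_match(de, "cnt", min_count = 0), "min_count")
})

test_that("splitting by gene set tallies unmatched ids", {
  de <- make_de(paste0("g", 1:4), c(-1, -2, -3, 1))
  s <- split_by_gene_set(de, c("g2", "g9"))
  expect_equal(s$match_values, -2)
  expect_equal(length(s$background_values), 3L)
  expect_equal(s$tally$unmatched_set_ids, 1L)
  expect_error(split_by_gene_set(de, paste0("g", 1:4)), "background group")
  expect_error(split_by_gene_set(de, c("x1", "x2")), "no gene in the set")
  f <- withr::local_tempfile(lines = c("# targets", "g2", "", "g9"))
  s2 <- split_by_gene_set(de, f)
  expect_equal(s2$match_values, s$match_values)
})

test_that("the ECDF step table is right-continuous with F(x)=#(<=x)/n", {
  tab <- ecdf_table(c(1, 2, 2, 3))
  expect_equal(tab$x, c(1, 2, 3))
  expect_equal(tab$F, c(0.25, 0.75, 1))
  expect_equal(max(tab$F), 1)
  vals <- rnorm(20)
  tab2 <- ecdf_table(vals)
  f <- stats::ecdf(vals)  # base R as independent reference
  expect_equal(tab2$F, unname(f(tab2$x)))
  expect_error(ecdf_table(c(NA, Inf)), "no finite values")
})

test_that("KS results on degenerate splits take their boundary values", {
  vals <- c(-1, 0, 1, 2)
  same <- make_split(vals, vals)
  r <- ks_ecdf_test(same)
  expect_equal(r$d_stat, 0)
  expect_equal(r$p_value, 1)
  sep <- make_split(c(-5, -4, -3), c(1, 2, 3))
  expect_equal(ks_ecdf_test(sep)$d_stat, 1)
  expect_error(ks_ecdf_test(make_split(c(1, 2), c(3, 4, 5))),
               "below the minimum")
})

test_that("the one-sided asymptotic p follows exp(-2 D^2 mn/(m+n))", {
  expect_equal(sirnaseed:::ks_asymptotic_p(0.2, 100, 100, "match-down"),
               exp(-4), tolerance = 1e-12)
  # non-increasing in D at fixed sizes
  d <- seq(0.05, 0.8, by = 0.05)
  p <- vapply(d, sirnaseed:::ks_asymptotic_p, numeric(1), m = 50, n = 80,
              alternative = "match-down")
  expect_true(all(diff(p) < 0))
})

test_that("D equals the direct sup oracle for all alternatives", {
  set.seed(31)
  for (i in 1:80) {
    m <- sample(3:30, 1); n <- sample(3:30, 1)
    x <- round(rnorm(m, sd = 2), sample(0:2, 1))  # rounding induces ties
    y <- round(rnorm(n, mean = 0.4, sd = 2), sample(0:2, 1))
    for (alt in c("match-down", "match-up", "two-sided")) {
      expect_equal(sirnaseed:::ks_d_stat(x, y, alt), brute_ks_d(x, y, alt),
                   info = paste("alt =", alt))
    }
  }
})

test_that("D and p agree with stats::ks.test on tie-free data", {
  set.seed(32)
  for (i in 1:25) {
    m <- sample(4:40, 1); n <- sample(4:40, 1)
    x <- rnorm(m); y <- rnorm(n, 0.3)
    s <- make_split(x, y)
    mine <- ks_ecdf_test(s, "match-down", p_method = "exact")
    ref <- ks.test(x, y, alternative = "greater")
    expect_equal(mine$d_stat, unname(ref$statistic))
    if (mine$p_method == "exact" && m * n < 10000)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    two <- ks_ecdf_test(s, "two-sided", p_method = "exact")
    ref2 <- ks.test(x, y)
    expect_equal(two$d_stat, unname(ref2$statistic))
    if (two$p_method == "exact")
      expect_equal(two$p_value, ref2$p.value, tolerance = 1e-12)
  }
  # large samples: R's one-sided asymptotic p is the same exponential bound
  xb <- rnorm(150); yb <- rnorm(180, 0.2)
  big <- ks_ecdf_test(make_split(xb, yb))
  refb <- suppressWarnings(ks.test(xb, yb, alternative = "greater",
                                   exact = FALSE))
  expect_equal(big$p_value, refb$p.value, tolerance = 1e-12)
})

test_that("exact path-counting p matches stats::psmirnov", {
  set.seed(33)
  for (i in 1:20) {
    m <- sample(3:25, 1); n <- sample(3:25, 1)
    x <- rnorm(m); y <- rnorm(n, 0.5)
    d <- sirnaseed:::ks_d_stat(x, y, "match-down")
    expect_equal(sirnaseed:::ks_exact_p(d, m, n, "match-down"),
                 1 - stats::psmirnov(d, sizes = c(m, n), two.sided = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("exact method falls back to asymptotic on ties or big samples", {
  s <- make_split(c(1, 2, 3, 3), c(3, 4, 5))
  expect_warning(r <- ks_ecdf_test(s, p_method = "exact"), "ties")
  expect_equal(r$p_method, "asymptotic")
  big <- make_split(rnorm(150), rnorm(150))
  expect_warning(r2 <- ks_ecdf_test(big, p_method = "exact"), "10000")
})

test_that("the KS statistic is location invariant and label-symmetric", {
  set.seed(34)
  x <- rnorm(40); y <- rnorm(60, 0.3)
  a <- ks_ecdf_test(make_split(x, y))
  b <- ks_ecdf_test(make_split(x + 7, y + 7))
  expect_equal(a$d_stat, b$d_stat)
  expect_equal(a$p_value, b$p_value)
  t1 <- ks_ecdf_test(make_split(x, y), "two-sided")
  t2 <- ks_ecdf_test(make_split(y, x), "two-sided")
  expect_equal(t1$d_stat, t2$d_stat)
  # two-sided D dominates each one-sided D
  expect_gte(t1$d_stat, ks_ecdf_test(make_split(x, y), "match-down")$d_stat)
  expect_gte(t1$d_stat, ks_ecdf_test(make_split(x, y), "match-up")$d_stat)
})

test_that("non-finite fold changes are rejected before testing", {
  s <- make_split(c(1, 2, 3), c(4, 5, 6))
  s$match_values[1] <- NA
  expect_error(ks_ecdf_test(s), "non-finite")
})

test_that("the one-call off-target pipeline is deterministic", {
  pat <- get_seed("UUAUAGAGCAAGAACACUGUUUU", "mer7m8")
  set.seed(35)
  n <- 40
  hit <- rep(c(TRUE, FALSE), c(10, 30))
  seqs <- vapply(seq_len(n), function(i) {
    s <- rand_dna_chr(60)
    if (hit[i]) substr(s, 20, 26) <- pat$target_dna
    s
  }, "")
  # make sure background sequences really lack the site
  seqs[!hit] <- vapply(seqs[!hit], function(s)
    gsub(pat$target_dna, "ACGTACG", s, fixed = TRUE), "")
  fs <- make_feature_seqs(sprintf("g%02d", 1:n), sprintf("t%02d", 1:n), seqs)
  de <- make_de(sprintf("g%02d", 1:n), rnorm(n) - 0.6 * hit)
  r1 <- run_offtarget_test(de, guide_sequence("UUAUAGAGCAAGAACACUGUUUU",
                                              "g1"), fs)
  r2 <- run_offtarget_test(de, guide_sequence("UUAUAGAGCAAGAACACUGUUUU",
                                              "g1"), fs)
  expect_identical(r1$ks, r2$ks)
  expect_equal(sort(r1$split$match_ids), sprintf("g%02d", 1:10))
  expect_s3_class(r1$de, "data.frame")
  expect_true(paste0("g1.mer7m8") %in% names(r1$de))
})
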