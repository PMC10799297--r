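---
title: "Detecting siRNA seed-mediated off-target effects from differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting siRNA seed-mediated off-target effects from differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnaseed)
```

## The model

An siRNA guide strand loaded into AGO can repress transcripts it was never
designed against when its seed region — approximately guide positions 1–8
from the 5' end — pairs with sites in their 3' UTRs, the binding mode that
miRNAs use. Each individual interaction is weak; what an RNA-seq
experiment can detect is the *aggregate*: if a guide has seed-driven
activity, the set of genes whose 3' UTR contains a seed-complementary
site should show a small systematic shift toward negative log2 fold
changes relative to genes without a site.

`sirnaseed` operationalizes this as a two-group comparison. Genes in the
(filtered) DE table are split into a **match** group (seed target pattern
occurs in the gene's chosen feature sequence) and a **background** group
(it does not), and the empirical cumulative distribution functions of
their log2 fold changes are compared with a one-sided two-sample
Kolmogorov–Smirnov statistic,

$$D = \sup_x\,[\,F_{\text{match}}(x) - F_{\text{bg}}(x)\,],$$

large when the match group's distribution sits to the left of (is
stochastically smaller than) the background. The test is distribution-free:
it makes no assumption about the shape of the fold-change distribution,
only exchangeability of genes under the null. It does assume genes are
independent, which RNA-seq fold changes only approximate (co-regulation,
shared normalization); p-values should be read as a ranking-quality
screen, not a calibrated error rate on real data.

### Seed definitions

The four canonical site types are windows on the guide plus an optional
adenine opposite guide position 1:

| name   | guide window | appended A | target length |
|--------|--------------|------------|---------------|
| mer8   | 2–8          | yes        | 8             |
| mer7m8 | 2–8          | no         | 7             |
| mer7A1 | 2–7          | yes        | 7             |
| mer6   | 2–7          | no         | 6             |

The DNA target pattern is the reverse complement of the seed window
(U→T), with the A appended to the pattern's 3' end, so the site on the
transcript reads 5'-(seed complement)A-3'. Position 1 itself is never
required to pair — A-U pairing at that position is recognized by AGO via
the adenine on the mRNA, which is why the A is unconditional in mer8 and
mer7A1 rather than being complemented from the guide. `mer7m8` is the
default: it is the most specific site type that does not condition on
the position-1 adenine. Custom windows (`custom_seed()`) support
exploratory definitions; coordinates are 1-based inclusive with position
1 = the guide's 5' nucleotide, the convention in which seed positions
("g2–g8") are quoted in the field.

## Feature sequences

Matching runs against transcript-oriented feature sequences built from a
GTF and genome FASTA. Internally every interval lives in a `GRanges`
(1-based inclusive); `rtracklayer` converts at the GTF boundary. We chose
the field's canonical container over a bespoke 0-based layer because all
arithmetic (`restrict`, `psetdiff`, `promoters`) then happens in one
audited coordinate system, which removes the same off-by-one risk a
custom convention would.

* **3' UTR** (default feature): explicit `three_prime_utr` records when
  the GTF has them, otherwise the exonic region strictly 3' of the CDS
  end in transcript orientation. When `stop_codon` records exist, the CDS
  is first extended by them, so Ensembl-style annotations (stop codon
  excluded from CDS) and inclusive dialects infer identical UTRs. If a
  transcript's CDS runs to its end, it has no 3' UTR and is omitted —
  omissions are tallied, and genes with no surviving transcript get match
  count 0 downstream so the background group keeps them (treating "no
  UTR" as "no site" rather than silently shrinking the universe).
* **Introns**: gaps between a transcript's exons.
* **Promoters**: `[TSS − upstream, TSS + downstream)` in transcript
  orientation, defaults 2000 nt upstream / 200 nt downstream — the
  long-standing default promoter window in the Bioconductor ecosystem.
  Windows running off a contig are clipped with a warning (counted in
  `n_clipped`). This feature type supports small-activating-RNA analyses,
  where the hypothesized shift is *upward* (`alternative = "match-up"`).
* Minus-strand features are reverse-complemented and spliced pieces are
  concatenated in transcript 5'→3' order, so every sequence reads as the
  transcript does. Chromosome naming differences ("chr1" vs "1") are
  reconciled by a prefix-aliasing pass; anything still missing is an
  error rather than a silent drop.

## Match counting

Counting uses `Biostrings::vcountPattern` semantics: every alignment
start position with at most `max_mismatch` substitutions counts,
overlapping occurrences included (a deliberate choice — it affects counts
for low-complexity seeds such as `TTTTTTT`, and is documented for that
reason). Comparison is case-insensitive; any pairing that involves a
non-ACGT letter (N, ambiguity codes) is a mismatch; alignments must lie
entirely within the sequence (alignments overhanging the ends, which the
underlying matcher reports when mismatches are allowed, are excluded).
Indels and G:U wobble pairing are out of scope; the default
`max_mismatch = 0` reflects exact seed matching.

Per-gene aggregation across transcripts is a genuinely open design
point — isoform-rich genes would otherwise dominate any "sum" — so it is
a policy argument. The default, **max over byte-identical-deduplicated
transcript sequences**, preserves the binary has-a-site/has-no-site split
the KS comparison actually consumes while not rewarding isoform count;
`sum` and `longest` are available for users who want site dosage or a
single-representative convention. Deduplication first means shared UTRs
across isoforms are never double-counted under `sum`.

## The gene universe and the test

`filter_de_results()` makes the tested universe explicit: defaults are
permissive (`padj_cutoff = 1`, `fc_cutoff = 0`, `base_mean_min = 0`,
`drop_na = TRUE`) and every rule reports how many rows it removed. NA
fold changes must go before testing — the statistic is undefined for
them — and the filter report keeps that auditable.

`ks_ecdf_test()` evaluates both ECDFs at the pooled sorted unique values,
which makes $D$ well-defined under ties (shrunken log2 fold changes can
tie exactly). The alternative is named by the scientific claim rather
than by CDF inequalities: `match-down` (default) means match-group values
stochastically smaller, i.e. the match ECDF lies *above* the background
ECDF — the naming sidesteps the classic less/greater ambiguity of
one-sided KS conventions. P-values use the one-sided asymptotic bound
$p = \exp(-2D^2mn/(m+n))$ by default (the Kolmogorov series for
`two-sided`); gene-scale group sizes make this standard. For small
samples (`p_method = "exact"`, $mn \le 10{,}000$, tie-free) an exact
lattice-path enumeration is used: under the null all merge orders of the
two samples are equally likely, and dynamic programming counts the paths
whose running ECDF difference stays below the observed $D$. The
asymptotic bound is slightly conservative at moderate sizes (empirical
size ≈ 0.043–0.047 at nominal 0.05 for 100 vs 400); this is inherent to
the exponential bound, not a coding artifact, and is visible in the null
calibration the acceptance script recomputes. A minimum group size of 3
per group (configurable) is an artifact policy guarding against vacuous
comparisons, not a statistical threshold.

## What the synthetic fixtures emulate

`generate_fixture()` builds a toy genome, GTF, DE table and truth table
in which the *mechanism* is real but everything incidental is idealized:

* Each gene has a two-exon transcript (CDS split across both exons, UTR
  on the last exon) and, with probability 0.3, an alternative-TSS isoform
  sharing the UTR — enough structure to exercise splicing, strand
  handling (half the genes are minus-strand), UTR inference and
  transcript deduplication.
* Match genes receive 1–3 planted exact target sites in the 3' UTR;
  background UTRs are rejection-sampled to contain zero occurrences, so
  the truth table is unambiguous and exact recovery is a testable
  property rather than a probabilistic one.
* Fold changes are `Normal(-delta * is_match, sigma)`. The KS test is
  distribution-free, so the noise family is a convenience, not a claim
  about DESeq2 output; `padj` (BH-adjusted two-sided z approximation)
  and `baseMean` (log-normal) are plausible placeholders that exercise
  the filter paths, nothing more.
* Defaults — 500 genes, 100 match genes, shift `delta = 0.3` log2 units,
  noise `sigma = 0.5` log2 units — are the package's reference validation
  scenario: an effect of 0.6 noise-standard-deviations across a fifth of
  a 500-gene universe, the size of shift seed-mediated activity produces
  in practice, where the one-sided test at α = 0.05 has power near 1
  while `delta = 0` calibrates its size.

What the fixtures deliberately do **not** emulate: read-level counting
noise and dispersion estimation (inputs begin at the DE-results table,
where the tool's inputs begin), correlated fold changes, 3' UTR sequence
composition bias, partial or mismatched sites in background genes, and
isoform-specific expression. Passing tests therefore demonstrate
correctness of the machinery and calibration/power under idealized
exchangeable noise — not that real experiments meet the test's
independence assumptions.

`simulate_power()` replicates only the fold-change layer (match statuses
fixed, draws re-sampled): given match status, the genome/GTF layer is
deterministic and contributes nothing to the distribution of the
statistic, so simulating it thousands of times would add runtime without
information. Problem sizes used by the shipped validation: 10,000
replicates for the null size check, 200 for power, 1,000 random instances
for the string-matching oracle, samples of up to 30 per group for the
exact-statistic oracle.

## Known limitations

* GTF only (no GFF3), one annotation dialect family auto-detected via
  `stop_codon` records; trans-spliced or circular transcripts are not
  modelled.
* Exact-string matching with optional substitutions — no wobble pairs, no
  indels, no thermodynamic or context scoring; the match count is a site
  census, not an affinity prediction.
* One test per run: no multiple-testing correction across guides or seed
  definitions is applied or implied.
* The asymptotic one-sided p-value is a bound, mildly conservative at
  moderate group sizes (see above).
* Gene IDs are taken as-is from the GTF and DE table; no identifier
  translation is attempted, so the two inputs must share an ID space.
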