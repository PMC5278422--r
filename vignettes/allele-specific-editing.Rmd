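---
title: "Methods: allele-specific CRISPR site discovery and editing quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific CRISPR site discovery and editing quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprAllele)
```

This vignette is the package's own account of the methods it
implements: the model of the experiment, each procedural choice and
its default parameters, the numerical decisions, and the known
limitations.

## 1. The experimental model

The package targets experiments in diploid hybrids of two
deep-sequenced strains. Heterozygous strain-distinguishing SNVs play
two distinct roles:

- **Targeting**: an SNV inside a CRISPR/Cas9 protospacer or inside the
  PAM's two guanines makes a guide allele-discriminating — one
  chromosome is a perfect target, the other carries a mismatch or a
  broken PAM.
- **Readout**: a heterozygous *diagnostic SNP* inside the sequenced
  amplicon assigns each read to a parental chromosome, so editing
  rates can be measured per allele.

The quantities of interest are per-allele edited-read percentages, the
2x2 edited-by-allele contingency test, loxP knock-in rates, and — for
paired-guide designs — the fraction of deletion-junction reads per
allele.

## 2. Genome scan

`scan_pam_sites()` enumerates every 23-nt window whose positions 21–22
(0-based window offsets 21 and 22) are `GG` on the forward strand, and
every window beginning `CC` for the reverse strand, reporting the
protospacer (20 nt) and PAM (3 nt) in strand orientation with 0-based
half-open genomic coordinates. Overlapping `GG` runs each count: a run
of *k* consecutive `G`s yields *k − 1* anchors, provided 21 nt of 5'
flank exist. Windows containing `N` are dropped by default
(`n_policy = "drop"`); `"keep"` retains them for masked-assembly
bookkeeping.

`mark_strain_specific()` intersects sites with a biallelic SNV table.
A site/variant pair is retained when the variant falls inside the
protospacer or on either PAM `G`. The PAM `N` (window offset 20) is
excluded: it is unconstrained by SpCas9, so a variant there does not
discriminate alleles. `distance_from_pam` runs from 20 (protospacer
position farthest from the PAM) to 0 (inside the PAM `GG`), computed
in strand orientation.

`annotate_sites()` reports four counts against a coding-exon table:
sites overlapping a coding exon (`exon_hit_count`, by interval
intersection of the 23-nt window), genes with at least one site in a
coding exon, genes with at least one site anywhere in their span, and
genes where some coding exon has sites strictly on both its 5' and 3'
sides within the gene span (`gene_flanking_count`) — the substrate for
two-cut exon-deletion designs. *Open design decision*: "flanking" is
defined as the whole site window lying outside the exon on each side;
a looser midpoint-based definition would count a handful of
boundary-straddling sites differently.

Site scoring is a pluggable hook (`score_sites()` with
`scorer_uniform()` as default). No empirical guide-efficiency model is
shipped — published scoring schemes are training-data-specific, so the
package exposes the interface rather than hard-coding one.

## 3. Amplicon pipeline

**Trimming** (`trim_quality()`) follows the classical
leading/trailing/sliding-window scheme with defaults `leading = 5`,
`trailing = 5`, a 10-base window requiring mean quality ≥ 30, and
`min_len = 75`. The window rule cuts at the start of the first failing
window, then extends the kept prefix over bases that individually pass
the threshold. Optional adapter clipping removes 3' read-through by
suffix overlap (≥ 4 nt, ≤ 1 mismatch per 10 nt).

**Merging** (`merge_pairs()`) truncates each mate at its first base
with quality ≤ `trunc_qual` (default 3), then searches for the longest
ungapped overlap between the end of mate 1 and the reverse complement
of mate 2, requiring ≥ `min_overlap` (50) bases and ≤ `max_diffs` (0)
mismatches; the consensus takes the higher-quality base at each
overlap position. Defaults mirror widely used amplicon-merging
settings; `max_diffs = 0` is deliberately strict so that downstream
indel calls never rest on ambiguous consensus bases. Swapping the
mates yields the reverse complement of the same consensus — the
physically meaningful symmetry, verified by property test.

**Alignment** (`align_glocal()`) is *glocal*: global in the read, with
free end gaps in the reference — appropriate because a merged read is
a complete molecule that may cover only part of the amplicon
reference. Scoring: match +2, mismatch −4, affine gaps costing
`gap_open + L * gap_extend` = −6 − L for a length-*L* gap. These
values make a single mismatch (−4) cheaper than a 1-nt gap pair and an
indel of a few nt cheaper than several mismatches, which is the right
trade-off for Cas9 outcomes (indels at the cut site, substitutions
only from sequencing error). The implementation is a three-state Gotoh
dynamic program in C++ with deterministic tie-breaking; reported
indels are then left-normalised (shifted 5' through repeat context) so
identical molecules always produce identical operation tables. An
independent full-matrix R implementation and
`Biostrings::pairwiseAlignment(type = "global-local")` serve as test
oracles.

Pre-aligned reads are accepted via text SAM (`load_alignments()`),
with CIGAR `M` split into match/mismatch against the target reference,
unmapped/secondary/supplementary records skipped and counted, and
malformed records reported with their line number.

## 4. Edit counting and allele assignment

`assign_allele()` reads the base aligned to the diagnostic SNP
position. Reads whose diagnostic base is deleted, not covered, or
matches neither strain are **indeterminate** rather than guessed.
When a loxP knock-in is configured, the donor-specific SNP is checked
*first*: a read carrying the donor base is recombination-derived and
cannot be attributed to either parental chromosome. The accounting
invariant `strain A + strain B + indeterminate = total` is asserted
inside `summarize_locus()` on every run.

`classify_edit()` calls a read edited when an insertion or deletion
overlaps the edit window (default: protospacer plus PAM, 23 nt).
Deletions overlap by interval intersection; an insertion counts when
its point falls inside the window or on either boundary.
Substitutions never count — they are indistinguishable from
sequencing error at typical error rates.

`detect_loxp()` flags a read as knock-in positive when it contains any
10-mer of the 34-nt loxP sequence
(`ATAACTTCGTATAGCATACATTATACGAAGTTAT`). The 10-mer rule tolerates
partial integrations and junction-truncated reads at the cost of
permissiveness; the expected chance hit rate for a ~200-nt read is
~25 × 190 / 4^10 ≈ 0.5%, acceptable for screening and exactly zero
false negatives on error-free data (verified in the acceptance tests).
A caveat discovered during testing: loxP's 13-bp inverted repeats mean
its reverse complement shares 10-mers with the forward site, so
rc-oriented reads are detected even without `both_strands = TRUE`;
that flag matters only for non-palindromic donor sequences.

`classify_deletion_read()` calls a junction read when the alignment to
the fused junction reference has ≥ `min_side` (10) matched bases on
each side of the fusion coordinate — enough to exclude reads that
merely end near the junction.

`compare_alleles()` builds the edited/unedited × strain-A/strain-B
table (indeterminate reads excluded, since they have no chromosome of
origin) and applies the plain Pearson chi-squared test
(`chi_squared_2x2()`, continuity correction off by default, exposed as
a flag). `fisher_exact_2x2()` is provided for small or zero-margin
tables; both are thin wrappers over base R's `chisq.test`/
`fisher.test`, validated in the test suite against a closed-form
Pearson statistic and explicit hypergeometric enumeration.

## 5. Synthetic data and its realism

`simulate_edited_amplicons()` plants, per read pair: an allele
(probability `allele_ratio`, default 0.5), an indel at the cut site
with the allele's rate (insertion or deletion equally likely, length
1 + Geometric(0.5) truncated at 20 — matching the empirical dominance
of 1–3-nt NHEJ indels), optionally a loxP insertion at the cut with
the donor SNP converted with probability `loxp_snp_conversion`
(default 0.5, modelling partial HDR conversion tracts), and uniform
substitution sequencing error (`error_rate = 0.001`). Mates read the
two fragment ends (`read_length = 130`) with constant quality 37.

Deliberate simplifications: no quality-score decay along the read, no
microhomology-biased deletion spectrum, no PCR duplicates or chimeras,
blunt cuts exactly between protospacer positions 17/18. These do not
affect what the simulator is for — end-to-end validation with known
truth — but mean recovery accuracy on real data will be somewhat worse
than on simulated data. The geometry guard
`2 * read_length >= ref_len + max_indel + 50` ensures every simulated
pair can merge, so pipeline losses come only from planted errors.

## 6. Numerical and interface choices

- Coordinates are 0-based half-open everywhere internally; BED output
  is native, VCF positions are converted on input.
- The aligner guards against quadratic blow-up (`n * m > 2.5e8`
  cells is an error) — it is an amplicon aligner, not a genome
  aligner.
- Percentages over zero-read classes are `NA`, never `NaN`.
- All generators accept explicit seeds and restore the caller's RNG
  state; the acceptance script derives every stream from one `--seed`.

## 7. Known limitations

- Substitution-only editing outcomes (base editing, prime editing)
  are out of scope.
- Guide efficiency scoring is an interface, not a model.
- The loxP rule cannot distinguish forward from inverted integrations
  (inherent to the palindromic site).
- SAM ingestion trusts the aligner's primary-alignment choice; no
  re-alignment or MAPQ filtering is applied beyond flag-based
  skipping.
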