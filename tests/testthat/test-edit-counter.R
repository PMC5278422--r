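# A minimal aligned-read stub: the classifier functions only consume
# the documented fields (id, seq, ops, ref_start, ref_end).
mk_aln <- function(seq, ops, ref_start, ref_end, id = "r") {
  structure(list(id = id, seq = seq, score = NA_real_, ops = ops,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 read_len = nchar(seq)),
            class = "aligned_read")
}
op_row <- function(op, len, ref_pos) {
  data.frame(op = op, len = as.integer(len), ref_pos = as.integer(ref_pos),
             stringsAsFactors = FALSE)
}

mk_cls <- function(allele, edited, loxp = FALSE, junction = NA) {
  n <- length(allele)
  out <- data.frame(id = sprintf("r%03d", seq_len(n)), allele = allele,
                    edited = edited, loxp_positive = rep_len(loxp, n),
                    junction = rep_len(junction, n), stringsAsFactors = FALSE)
  attr(out, "indels") <- data.frame(kind = character(0), len = integer(0),
                                    ref_pos = integer(0),
                                    read_id = character(0),
                                    stringsAsFactors = FALSE)
  class(out) <- c("read_classifications", "data.frame")
  out
}

test_that("amplicon_target validates geometry and the loxP spec", {
  t <- synthetic_target(seed = 41)
  expect_s3_class(t, "amplicon_target")
  expect_equal(diff(t$protospacer_span), 20L)
  expect_equal(substr(t$ref_seq, t$pam_span[1] + 2L, t$pam_span[2]), "GG")
  expect_equal(t$cut_offset, t$protospacer_span[2] - 3L)
  expect_equal(t$edit_window, c(t$protospacer_span[1], t$pam_span[2]))

  expect_error(
    amplicon_target("x", strrep("A", 50), c(10, 30), snp_offset = 15,
                    strain_a_base = "A", strain_b_base = "C"),
    "PAM")
  expect_error(
    amplicon_target("x", paste0(strrep("A", 31), "GG", strrep("A", 17)),
                    c(10, 30), snp_offset = 15,
                    strain_a_base = "A", strain_b_base = "A"),
    "distinct")
  tl <- synthetic_target(seed = 42, loxp = TRUE)
  expect_false(tl$loxp$snp_base %in% c(tl$strain_a_base, tl$strain_b_base))
  # a loxP SNP equal to a strain base is rejected
  expect_error(
    amplicon_target("x", tl$ref_seq, tl$protospacer_span,
                    snp_offset = tl$snp_offset,
                    strain_a_base = tl$strain_a_base,
                    strain_b_base = tl$strain_b_base,
                    loxp = list(seq = LOXP_SEQ,
                                snp_base = tl$strain_a_base)),
    "differ from both strain bases")
})

test_that("assign_allele reads the diagnostic base and handles edge cases", {
  t <- synthetic_target(seed = 43)
  snp <- t$snp_offset
  ref_a <- t$ref_seq                                  # carries strain A base
  ref_b <- paste0(substr(ref_a, 1, snp), t$strain_b_base,
                  substr(ref_a, snp + 2, nchar(ref_a)))
  a <- align_glocal(substr(ref_a, snp - 19, snp + 21), ref_a)
  expect_equal(assign_allele(a, t), "strain_a")
  b <- align_glocal(substr(ref_b, snp - 19, snp + 21), ref_a)
  expect_equal(assign_allele(b, t), "strain_b")

  # SNP not covered by the read
  off <- align_glocal(substr(ref_a, snp + 5, snp + 44), ref_a)
  expect_equal(assign_allele(off, t), "indeterminate")

  # SNP base deleted
  del <- mk_aln(strrep("A", 20),
                rbind(op_row("match", 10, snp - 10),
                      op_row("deletion", 3, snp),
                      op_row("match", 10, snp + 3)),
                snp - 10, snp + 13)
  expect_equal(assign_allele(del, t), "indeterminate")

  # base matching neither strain (simulate via a third base at the SNP)
  third <- setdiff(c("A", "C", "G", "T"),
                   c(t$strain_a_base, t$strain_b_base))[1]
  ref_x <- paste0(substr(ref_a, 1, snp), third,
                  substr(ref_a, snp + 2, nchar(ref_a)))
  x <- align_glocal(substr(ref_x, snp - 19, snp + 21), ref_a)
  expect_equal(assign_allele(x, t), "indeterminate")
})

test_that("loxP-specific SNP overrides the diagnostic base", {
  t <- synthetic_target(seed = 44, loxp = TRUE)
  snp <- t$snp_offset
  ref_lox <- paste0(substr(t$ref_seq, 1, snp), t$loxp$snp_base,
                    substr(t$ref_seq, snp + 2, nchar(t$ref_seq)))
  a <- align_glocal(substr(ref_lox, snp - 19, snp + 21), t$ref_seq)
  expect_equal(assign_allele(a, t), "indeterminate")
  # without the donor base, assignment proceeds normally
  b <- align_glocal(substr(t$ref_seq, snp - 19, snp + 21), t$ref_seq)
  expect_equal(assign_allele(b, t), "strain_a")
})

test_that("classify_edit applies interval-overlap rules exactly", {
  t <- synthetic_target(seed = 45)
  ws <- t$edit_window[1]; we <- t$edit_window[2]
  aln_with <- function(ops) mk_aln(strrep("A", 50), ops, 0, nchar(t$ref_seq))

  # deletion ending exactly at the window start: no overlap
  expect_false(classify_edit(
    aln_with(op_row("deletion", 5, ws - 5)), t)$edited)
  # deletion protruding one base into the window: edited
  expect_true(classify_edit(
    aln_with(op_row("deletion", 5, ws - 4)), t)$edited)
  # deletion starting at the window end: no overlap
  expect_false(classify_edit(
    aln_with(op_row("deletion", 5, we)), t)$edited)
  # insertion exactly on either boundary counts
  expect_true(classify_edit(aln_with(op_row("insertion", 2, ws)), t)$edited)
  expect_true(classify_edit(aln_with(op_row("insertion", 2, we)), t)$edited)
  expect_false(classify_edit(
    aln_with(op_row("insertion", 2, we + 1)), t)$edited)
  # substitutions never count
  expect_false(classify_edit(
    aln_with(op_row("mismatch", 23, ws)), t)$edited)
  # indels outside the window are still inventoried
  ce <- classify_edit(aln_with(op_row("deletion", 2, 0)), t)
  expect_false(ce$edited)
  expect_equal(nrow(ce$indels), 1L)
})

test_that("detect_loxp implements k-mer containment with a sharp boundary", {
  full <- paste0(strrep("C", 20), LOXP_SEQ, strrep("C", 20))
  ten <- paste0(strrep("C", 20), substr(LOXP_SEQ, 1, 10), strrep("C", 20))
  nine <- paste0(strrep("C", 20), substr(LOXP_SEQ, 1, 9), strrep("C", 20))
  none <- strrep("A", 60)
  got <- detect_loxp(c(full, ten, nine, none))
  expect_equal(got, c(TRUE, TRUE, FALSE, FALSE))
  # the 9-mer is found when k is lowered
  expect_true(detect_loxp(nine, k = 9))
  # k = 34 requires the full site
  expect_equal(detect_loxp(c(full, ten), k = 34), c(TRUE, FALSE))
  # monotonicity: smaller k can only add detections
  set.seed(46)
  reads <- vapply(1:30, function(i) {
    r <- rand_dna(80)
    if (i %% 3 == 0) r <- paste0(r, substr(LOXP_SEQ, 5, 5 + sample(8:33, 1)))
    r
  }, character(1))
  h12 <- detect_loxp(reads, k = 12)
  h10 <- detect_loxp(reads, k = 10)
  expect_true(all(h10 >= h12))
  # loxP's 13-bp inverted repeats make its reverse complement share
  # 10-mers with the forward site, so rc reads are detected either way
  expect_true(detect_loxp(revcomp(full)))
  # both_strands matters for a non-palindromic donor sequence
  asym <- paste0(strrep("A", 20), strrep("C", 14))
  rc_read <- paste0(strrep("G", 5), revcomp(asym), strrep("G", 5))
  expect_false(detect_loxp(rc_read, loxp_seq = asym))
  expect_true(detect_loxp(rc_read, loxp_seq = asym, both_strands = TRUE))
  expect_error(detect_loxp("ACGT", k = 0), "positive")
  expect_error(detect_loxp("ACGT", k = 35), "exceeds")
})

test_that("classify_deletion_read requires support on both junction sides", {
  t <- synthetic_target(seed = 47, deletion = TRUE)
  jp <- t$deletion$junction_pos
  jref <- t$deletion$junction_ref
  spanning <- align_glocal(substr(jref, jp - 29, jp + 30), jref)
  r <- classify_deletion_read(spanning, t)
  expect_true(r$junction)
  expect_equal(r$allele, "strain_a")

  # only 9 matched bases on the right: below min_side
  short <- align_glocal(substr(jref, jp - 29, jp + 9), jref)
  expect_false(classify_deletion_read(short, t)$junction)
  expect_equal(classify_deletion_read(short, t)$allele, "indeterminate")
  # ...but accepted if the threshold is lowered
  expect_true(classify_deletion_read(short, t, min_side = 9)$junction)

  # read entirely upstream of the junction
  up <- align_glocal(substr(jref, 1, jp - 5), jref)
  expect_false(classify_deletion_read(up, t)$junction)

  t_plain <- synthetic_target(seed = 47)
  expect_error(classify_deletion_read(spanning, t_plain), "deletion")
})

test_that("summarize_locus arithmetic and conservation hold", {
  t <- synthetic_target(seed = 48)
  cls <- mk_cls(
    allele = c(rep("strain_a", 10), rep("strain_b", 10),
               rep("indeterminate", 5)),
    edited = c(rep(TRUE, 4), rep(FALSE, 6),
               TRUE, rep(FALSE, 9), rep(FALSE, 5)))
  s <- summarize_locus(cls, t)
  expect_equal(s$n_total, 25L)
  expect_equal(unname(s$total), c(10L, 10L, 5L))
  expect_equal(sum(s$total), s$n_total)
  expect_equal(unname(s$edited_pct), c(40, 10, 0))
  expect_output(print(s), "25 reads")

  # percentages over empty classes are NA, not NaN or Inf
  s2 <- summarize_locus(mk_cls("strain_a", TRUE), t)
  expect_true(is.na(s2$edited_pct[["strain_b"]]))
  expect_equal(s2$edited_pct[["strain_a"]], 100)

  expect_error(summarize_locus(mk_cls(character(0), logical(0)), t),
               "no classified reads")
})

test_that("compare_alleles reproduces the closed-form chi-squared", {
  t <- synthetic_target(seed = 49)
  cls <- mk_cls(
    allele = c(rep("strain_a", 100), rep("strain_b", 100)),
    edited = c(rep(TRUE, 90), rep(FALSE, 10), rep(TRUE, 50), rep(FALSE, 50)))
  res <- compare_alleles(summarize_locus(cls, t))
  expect_equal(res$statistic, chi2_closed_form(90, 50, 10, 50),
               tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 38.095)
  expect_lt(res$p_value, 0.001)
  expect_equal(unname(res$table["edited", ]), c(90, 50))

  # an allele with zero reads cannot be tested by chi-squared
  one_sided <- summarize_locus(mk_cls(rep("strain_a", 5), rep(TRUE, 5)), t)
  expect_error(compare_alleles(one_sided), "fisher")
})

test_that("classify_reads ties the per-read calls together", {
  t <- synthetic_target(seed = 50, loxp = TRUE)
  cfg <- simulation_config(seed = 51, n_read_pairs = 120, loxp_rate = 0.3,
                           edit_rate_a = 0.2, edit_rate_b = 0.2,
                           error_rate = 0)
  sim <- simulate_edited_amplicons(t, cfg)
  res <- run_pipeline(t, sim)
  cls <- res$classifications
  truth <- sim$manifest[match(cls$id, sim$manifest$id), ]
  # loxP detection agrees with the planted truth exactly (error-free)
  expect_equal(cls$loxp_positive, truth$loxp)
  # loxP reads carrying the donor SNP are indeterminate; the remainder
  # keep their parental assignment
  conv <- truth$loxp & cls$allele == "indeterminate"
  kept <- truth$loxp & cls$allele != "indeterminate"
  expect_gt(sum(conv), 0)
  expect_gt(sum(kept), 0)
  expect_equal(cls$allele[kept], truth$allele[kept])
  # non-loxP reads: perfect allele agreement without errors
  plain <- !truth$loxp
  expect_equal(cls$allele[plain], truth$allele[plain])
  # planted indels are called edited
  expect_equal(cls$edited[plain],
               truth$edit_kind[plain] %in% c("insertion", "deletion"))
  # indel inventory covers every edited read
  inv <- attr(cls, "indels")
  expect_true(all(cls$id[cls$edited] %in% inv$read_id))
})
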