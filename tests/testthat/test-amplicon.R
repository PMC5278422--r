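mk_read <- function(seq, quals, id = "r1") {
  data.frame(id = id, seq = seq,
             qual = intToUtf8(as.integer(quals) + 33L),
             stringsAsFactors = FALSE)
}

test_that("quality trimming applies leading/trailing/window/minlen rules", {
  # uniform high quality: untouched
  r <- mk_read(rand_dna(100), rep(40, 100))
  out <- trim_quality(r)
  expect_equal(out$seq, r$seq)
  expect_equal(attr(out, "n_dropped"), 0L)

  # final 3 bases at Q2 removed by the trailing rule, rest kept
  r2 <- mk_read(rand_dna(100), c(rep(40, 97), rep(2, 3)))
  out2 <- trim_quality(r2)
  expect_equal(nchar(out2$seq), 97L)
  expect_equal(out2$seq, substr(r2$seq, 1, 97))

  # leading low-quality bases removed
  r3 <- mk_read(rand_dna(100), c(rep(2, 4), rep(40, 96)))
  expect_equal(nchar(trim_quality(r3)$seq), 96L)

  # sliding window cuts where the 10-base mean drops below 30 and
  # extends over individually good bases
  quals <- c(rep(40, 80), rep(10, 20))
  r4 <- mk_read(rand_dna(100), quals)
  out4 <- trim_quality(r4, min_len = 10)
  # first failing window starts before base 80; kept prefix extends to 80
  expect_equal(nchar(out4$seq), 80L)

  # a read cut below min_len is dropped
  r5 <- mk_read(rand_dna(100), c(rep(40, 60), rep(10, 40)))
  out5 <- trim_quality(r5)
  expect_equal(nrow(out5), 0L)
  expect_equal(attr(out5, "n_dropped"), 1L)

  expect_error(trim_quality(mk_read("ACGT", rep(40, 3))), "mismatch")
})

test_that("trimming never lengthens reads and keeps seq/qual in step", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(75:150, 1)
    r <- mk_read(rand_dna(n), sample(0:41, n, replace = TRUE))
    out <- trim_quality(r, min_len = 1)
    if (nrow(out)) {
      expect_lte(nchar(out$seq), n)
      expect_equal(nchar(out$seq), nchar(out$qual))
    }
  }
})

test_that("adapter clipping removes 3' adapter read-through", {
  adapter <- "AGATCGGAAGAGC"
  insert <- rand_dna(90)
  r <- mk_read(paste0(insert, adapter), rep(40, 90 + nchar(adapter)))
  out <- trim_quality(r, adapters = adapter)
  expect_equal(out$seq, insert)
  # partial adapter at the read end is also clipped
  r2 <- mk_read(paste0(insert, substr(adapter, 1, 6)), rep(40, 96))
  expect_equal(trim_quality(r2, adapters = adapter)$seq, insert)
})

mk_pair <- function(frag, rl, q1 = NULL, q2 = NULL) {
  l <- nchar(frag)
  s1 <- substr(frag, 1, rl)
  s2 <- revcomp(substr(frag, l - rl + 1, l))
  list(r1 = mk_read(s1, q1 %||% rep(40, rl)),
       r2 = mk_read(s2, q2 %||% rep(40, rl)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pair merging honours overlap length and mismatch limits", {
  frag <- rand_dna(140)
  p <- mk_pair(frag, 100)                       # 60-nt true overlap
  m <- merge_pairs(p$r1, p$r2)
  expect_equal(nrow(m$merged), 1L)
  expect_equal(m$merged$seq, frag)
  expect_equal(m$merged$overlap_len, 60L)
  expect_equal(nchar(m$merged$seq), 100L + 100L - 60L)

  # 49-nt overlap: below the minimum, unmerged
  frag2 <- rand_dna(151)
  p2 <- mk_pair(frag2, 100)
  m2 <- merge_pairs(p2$r1, p2$r2)
  expect_equal(nrow(m2$merged), 0L)
  expect_equal(m2$unmerged_ids, "r1")

  # one mismatch in a 60-nt overlap: rejected at max_diffs = 0,
  # accepted at max_diffs = 1
  p3 <- mk_pair(frag, 100)
  substr(p3$r1$seq, 70, 70) <- chartr("ACGT", "TGCA", substr(p3$r1$seq, 70, 70))
  expect_equal(nrow(merge_pairs(p3$r1, p3$r2)$merged), 0L)
  expect_equal(nrow(merge_pairs(p3$r1, p3$r2, max_diffs = 1)$merged), 1L)
})

test_that("truncation at low-quality tails precedes overlap search", {
  frag <- rand_dna(150)
  # mate 1 carries a Q2 base at position 91: read truncated to 90 nt,
  # leaving a 40-nt overlap -> unmerged
  q1 <- c(rep(40, 90), 2, rep(40, 9))
  p <- mk_pair(frag, 100, q1 = q1)
  expect_equal(nrow(merge_pairs(p$r1, p$r2)$merged), 0L)
  expect_equal(nrow(merge_pairs(p$r1, p$r2, min_overlap = 40)$merged), 1L)
  # a fully low-quality mate yields unmerged, not an error
  pempty <- mk_pair(frag, 100, q1 = rep(2, 100))
  expect_equal(nrow(merge_pairs(pempty$r1, pempty$r2)$merged), 0L)
})

test_that("swapping mates yields the reverse-complement consensus", {
  set.seed(22)
  for (i in 1:10) {
    frag <- rand_dna(sample(130:170, 1))
    p <- mk_pair(frag, 100)
    m12 <- merge_pairs(p$r1, p$r2)$merged
    m21 <- merge_pairs(p$r2, p$r1)$merged
    expect_equal(m21$seq, revcomp(m12$seq))
    expect_equal(m21$overlap_len, m12$overlap_len)
  }
})

test_that("glocal alignment recovers exact substrings and planted indels", {
  amp <- rand_dna(170)
  read <- substr(amp, 31, 130)
  a <- align_glocal(read, amp)
  expect_equal(nrow(a$ops), 1L)
  expect_equal(a$ops$op, "match")
  expect_equal(a$ref_start, 30L)
  expect_equal(a$ref_end, 130L)
  expect_equal(a$score, 200)

  # planted 3-nt deletion
  rd <- paste0(substr(amp, 31, 80), substr(amp, 84, 130))
  ad <- align_glocal(rd, amp)
  dels <- ad$ops[ad$ops$op == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$len, 3L)
  expect_equal(sum(ad$ops$len[ad$ops$op != "deletion"]), nchar(rd))

  # planted 4-nt insertion
  ri <- paste0(substr(amp, 31, 80), "TTTT", substr(amp, 81, 130))
  ai <- align_glocal(ri, amp)
  ins <- ai$ops[ai$ops$op == "insertion", ]
  expect_gte(nrow(ins), 1L)
  expect_equal(sum(ins$len), 4L)

  expect_error(align_glocal("", amp), "empty")
  expect_error(align_glocal("ACGU", amp), "outside")
})

test_that("alignment score equals the full-matrix DP oracle", {
  set.seed(23)
  for (i in 1:60) {
    amp <- rand_dna(sample(30:80, 1))
    rd <- rand_dna(sample(5:50, 1))
    expect_equal(align_glocal(rd, amp)$score, dp_glocal_score(rd, amp))
  }
  # reads derived from the amplicon with an edit
  for (i in 1:40) {
    amp <- rand_dna(80)
    rd <- substr(amp, 6, 75)
    p <- sample(20:40, 1)
    rd <- if (i %% 2) paste0(substr(rd, 1, p), substr(rd, p + 3, nchar(rd)))
          else paste0(substr(rd, 1, p), rand_dna(2), substr(rd, p + 1, nchar(rd)))
    expect_equal(align_glocal(rd, amp)$score, dp_glocal_score(rd, amp))
  }
})

test_that("indels are left-aligned deterministically", {
  # deletion inside a homopolymer run must sit at the run's 5' edge
  amp <- paste0(rand_dna(40), "CAAAAAG", rand_dna(40))
  rd <- paste0(substr(amp, 11, 41), "AAAA", substr(amp, 47, 77))  # one A lost
  a <- align_glocal(rd, amp)
  dels <- a$ops[a$ops$op == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$len, 1L)
  expect_equal(dels$ref_pos, 41L)     # first A of the run (0-based)
  # repeated runs give identical op tables
  b <- align_glocal(rd, amp)
  expect_identical(a$ops, b$ops)
})

test_that("read-consuming op lengths always sum to the read length", {
  set.seed(24)
  for (i in 1:40) {
    amp <- rand_dna(sample(40:90, 1))
    rd <- rand_dna(sample(8:60, 1))
    a <- align_glocal(rd, amp)
    consuming <- a$ops$op %in% c("match", "mismatch", "insertion")
    expect_equal(sum(a$ops$len[consuming]), nchar(rd))
    expect_true(all(diff(a$ops$ref_pos) >= 0))
  }
})

test_that("SAM ingestion reconstructs ops and skips non-primary records", {
  t <- synthetic_target(seed = 31)
  ref <- t$ref_seq
  read_m <- substr(ref, 11, 100)
  read_d <- paste0(substr(ref, 11, 50), substr(ref, 54, 100))
  sam <- c(
    "@HD\tVN:1.6",
    paste0("@SQ\tSN:", t$name, "\tLN:", nchar(ref)),
    paste("q1", 0, t$name, 11, 60, "90M", "*", 0, 0, read_m,
          strrep("F", nchar(read_m)), sep = "\t"),
    paste("q2", 0, t$name, 11, 60, "40M3D47M", "*", 0, 0, read_d,
          strrep("F", nchar(read_d)), sep = "\t"),
    paste("q3", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "FFFF", sep = "\t"),
    paste("q4", 256, t$name, 11, 60, "90M", "*", 0, 0, read_m,
          strrep("F", nchar(read_m)), sep = "\t")
  )
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  on.exit(unlink(path))
  alns <- load_alignments(path, list(t))
  expect_length(alns, 2L)
  expect_equal(attr(alns, "n_unmapped"), 1L)
  expect_equal(attr(alns, "n_secondary"), 1L)
  a1 <- alns[[1]]
  expect_equal(a1$ops$op, "match")
  expect_equal(a1$ops$len, 90L)
  expect_equal(a1$ref_start, 10L)
  a2 <- alns[[2]]
  expect_equal(a2$ops$op[a2$ops$op == "deletion"], "deletion")
  expect_equal(a2$ops$len[a2$ops$op == "deletion"], 3L)

  # malformed record reports its line number
  writeLines(c(sam, "broken\trecord"), path)
  expect_error(load_alignments(path, list(t)), "line 7")
})

test_that("error-free simulated pairs round-trip to all-match alignments", {
  t <- synthetic_target(seed = 32)
  cfg <- simulation_config(seed = 33, n_read_pairs = 40, error_rate = 0,
                           edit_rate_a = 0, edit_rate_b = 0)
  sim <- simulate_edited_amplicons(t, cfg)
  res <- run_pipeline(t, sim)
  expect_equal(nrow(res$classifications), 40L)
  expect_equal(res$n_unmerged, 0L)
  expect_false(any(res$classifications$edited))
})
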