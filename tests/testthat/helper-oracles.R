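# Independent oracle implementations used to cross-check the package.
# They deliberately share no code with the implementation under test.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Naive site scanner: position-by-position over a character vector.
# Emits the same columns as scan_pam_sites (N-containing windows kept
# or dropped to mirror the n_policy).
naive_scan <- function(genome, drop_n = TRUE) {
  rc1 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (chrom in names(genome)) {
    v <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(v)
    if (L < 23) next
    for (s in 0:(L - 23)) {                 # 0-based window start
      win <- v[(s + 1):(s + 23)]
      if (drop_n && any(win == "N")) next
      if (win[22] == "G" && win[23] == "G") {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = s, end = s + 23, strand = "+",
          protospacer = paste(win[1:20], collapse = ""),
          pam = paste(win[21:23], collapse = ""),
          stringsAsFactors = FALSE)
      }
      if (win[1] == "C" && win[2] == "C") {
        rcw <- rev(unname(rc1[win]))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = s, end = s + 23, strand = "-",
          protospacer = paste(rcw[1:20], collapse = ""),
          pam = paste(rcw[21:23], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Full-matrix affine-gap glocal DP, score only. Row-vectorised but
# otherwise a textbook three-state Gotoh with free reference end gaps;
# the reference-gap state is filled with a running-maximum recurrence.
dp_glocal_score <- function(read, ref, match = 2, mismatch = -4,
                            gap_open = -6, gap_extend = -1) {
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  fv <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(rv); m <- length(fv)
  go <- gap_open + gap_extend
  ge <- gap_extend
  M <- rep(0, m + 1)                 # row i-1; M[j+1] = score ending at j
  I <- rep(-Inf, m + 1)
  D <- rep(-Inf, m + 1)
  for (i in seq_len(n)) {
    s <- ifelse(rv[i] == fv, match, mismatch)
    best_prev <- pmax(M, I, D)
    Mi <- c(-Inf, best_prev[seq_len(m)] + s)
    if (i == 1) Mi <- c(-Inf, s)     # free start anywhere
    Ii <- pmax(M + go, I + ge, D + go)
    # D chains within the current row from M/I with affine cost: a run
    # of length L = j-k costs gap_open + L*ge, so
    # D[j] = ge*j + max_{k<j}(max(Mi,Ii)[k] + gap_open - ge*k)
    base <- pmax(Mi, Ii) + gap_open - ge * (0:m)
    Di <- c(-Inf, cummax(base[seq_len(m)])) + ge * (0:m)
    M <- Mi; I <- Ii; D <- Di
  }
  max(M, I)
}

# Exact Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins (choose() arithmetic only).
fisher_oracle <- function(a, b, c, d, sided = "two") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  p_obs <- probs[ks == a]
  if (sided == "one") sum(probs[ks >= a])
  else sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Vectorised variant of the naive checker for acceptance-scale inputs.
# Same definition, different mechanism again: logical masks over the
# character vector rather than a per-position loop or regex.
vector_scan <- function(genome, drop_n = TRUE) {
  revcomp23 <- function(x) {
    comp <- chartr("ACGTN", "TGCAN", x)
    do.call(paste0, lapply(23:1, function(i) substring(comp, i, i)))
  }
  rows <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(v)
    if (L < 23) next
    s0 <- 0:(L - 23)                       # 0-based window starts
    if (drop_n) {
      cn <- c(0L, cumsum(v == "N"))
      s0 <- s0[cn[s0 + 24L] - cn[s0 + 1L] == 0L]
      if (!length(s0)) next
    }
    f0 <- s0[v[s0 + 22L] == "G" & v[s0 + 23L] == "G"]
    r0 <- s0[v[s0 + 1L] == "C" & v[s0 + 2L] == "C"]
    mk <- function(st, strand) {
      if (!length(st)) return(NULL)
      w <- substring(seq, st + 1L, st + 23L)
      if (strand == "-") w <- revcomp23(w)
      data.frame(chrom = chrom, start = st, end = st + 23L, strand = strand,
                 protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- mk(f0, "+")
    rows[[length(rows) + 1L]] <- mk(r0, "-")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(naive_scan(setNames("", "x")))   # the canonical empty frame
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites_df <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), protospacer = character(0),
             pam = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Pearson chi-squared closed form for a 2x2 table
chi2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# run the full FASTQ -> summary pipeline in one call
run_pipeline <- function(target, sim, ...) {
  t1 <- trim_quality(sim$r1)
  t2 <- trim_quality(sim$r2)
  keep <- intersect(t1$id, t2$id)
  m <- merge_pairs(t1[match(keep, t1$id), ], t2[match(keep, t2$id), ], ...)
  ref <- if (!is.null(target$deletion)) target$deletion$junction_ref
         else target$ref_seq
  alns <- lapply(seq_len(nrow(m$merged)), function(i) {
    align_glocal(m$merged$seq[i], ref, id = m$merged$id[i])
  })
  cls <- classify_reads(alns, target)
  list(classifications = cls, summary = summarize_locus(cls, target),
       merged = m$merged, n_unmerged = length(m$unmerged_ids))
}
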