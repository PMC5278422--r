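# Amplicon read pipeline: quality trimming, overlap merging, glocal
# alignment against the amplicon reference, and SAM ingestion.

#' Quality-trim reads
#'
#' Applies, in order: optional adapter clipping (suffix-overlap match
#' against supplied adapter strings, allowing one mismatch per 10 nt of
#' overlap, minimum 4 nt), removal of leading and trailing bases below a
#' quality cutoff, 5'-to-3' sliding-window trimming (cut where the mean
#' quality of a full window drops below the threshold, then extend the
#' kept prefix over immediately following bases that individually meet
#' the threshold), and a minimum-length drop.
#'
#' Defaults correspond to `LEADING:5 TRAILING:5 SLIDINGWINDOW:10:30
#' MINLEN:75`.
#'
#' @param reads data frame with columns `id`, `seq`, `qual` (Phred+33),
#'   e.g. from [read_fastq()].
#' @param leading,trailing quality below which 5'/3' bases are removed.
#' @param window,window_min_mean sliding window size and mean-quality
#'   threshold.
#' @param min_len reads shorter than this after trimming are dropped.
#' @param adapters optional character vector of adapter sequences.
#' @return data frame of surviving (possibly shortened) reads, with
#'   attribute `n_dropped` giving the number of reads removed.
#' @export
trim_quality <- function(reads, leading = 5, trailing = 5, window = 10,
                         window_min_mean = 30, min_len = 75,
                         adapters = NULL) {
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch")
  }
  n <- nrow(reads)
  seqs <- character(n)
  quals <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    q <- decode_qual(reads$qual[i])
    if (!is.null(adapters)) {
      cut <- adapter_cut(s, adapters)
      if (!is.na(cut)) {
        s <- substr(s, 1L, cut - 1L)
        q <- q[seq_len(cut - 1L)]
      }
    }
    # leading
    len <- length(q)
    a <- 1L
    while (a <= len && q[a] < leading) a <- a + 1L
    # trailing
    b <- len
    while (b >= a && q[b] < trailing) b <- b - 1L
    if (b < a) { keep[i] <- FALSE; next }
    q <- q[a:b]
    s <- substr(s, a, b)
    # sliding window
    len <- length(q)
    if (len >= window) {
      cs <- cumsum(q)
      wm <- (cs[window:len] - c(0, cs[seq_len(len - window)])) / window
      fail <- which(wm < window_min_mean)
      if (length(fail)) {
        cutpt <- fail[1] - 1L             # keep bases 1..cutpt
        while (cutpt < len && q[cutpt + 1L] >= window_min_mean) {
          cutpt <- cutpt + 1L
        }
        q <- q[seq_len(cutpt)]
        s <- substr(s, 1L, cutpt)
      }
    }
    if (length(q) < min_len) { keep[i] <- FALSE; next }
    keep[i] <- TRUE
    seqs[i] <- s
    quals[i] <- encode_qual(q)
  }
  out <- data.frame(id = reads$id[keep], seq = seqs[keep],
                    qual = quals[keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# earliest read position at which a read suffix matches an adapter
# prefix with <= 1 mismatch per 10 nt of overlap (minimum overlap 4)
adapter_cut <- function(seq, adapters) {
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(sv)
  best <- NA_integer_
  for (ad in adapters) {
    av <- strsplit(ad, "", fixed = TRUE)[[1]]
    for (p in seq_len(max(len - 3L, 0L))) {
      ov <- min(len - p + 1L, length(av))
      if (ov < 4L) break
      mm <- sum(sv[p:(p + ov - 1L)] != av[seq_len(ov)])
      if (mm <= ov %/% 10L) {
        if (is.na(best) || p < best) best <- p
        break
      }
    }
  }
  best
}

#' Merge a mate pair by ungapped overlap
#'
#' Both mates are first truncated at the first base with quality at or
#' below `trunc_qual`. The forward read and the reverse complement of
#' the reverse mate are then searched for their longest ungapped overlap
#' with at most `max_diffs` mismatches and length at least
#' `min_overlap`; on success the consensus concatenation is returned,
#' the higher quality winning at overlapped positions.
#'
#' Defaults correspond to `-fastq_truncqual 3 -fastq_maxdiffs 0
#' -fastq_minovlen 50`.
#'
#' @param r1,r2 data frames of mates (columns `id`, `seq`, `qual`),
#'   matched row by row; `r2` holds the reverse-strand mates.
#' @param trunc_qual truncate each read at the first base with quality
#'   `<=` this value.
#' @param max_diffs maximum mismatches tolerated in the overlap.
#' @param min_overlap minimum overlap length.
#' @return list with `merged` (data frame `id`, `seq`, `qual`,
#'   `overlap_len`) and `unmerged_ids` (character vector).
#' @export
merge_pairs <- function(r1, r2, trunc_qual = 3, max_diffs = 0,
                        min_overlap = 50) {
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  ids <- character(n); seqs <- character(n); quals <- character(n)
  ovls <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_one(r1$seq[i], decode_qual(r1$qual[i]),
                   r2$seq[i], decode_qual(r2$qual[i]),
                   trunc_qual, max_diffs, min_overlap)
    if (is.null(m)) next
    ok[i] <- TRUE
    ids[i] <- r1$id[i]
    seqs[i] <- m$seq
    quals[i] <- encode_qual(m$qual)
    ovls[i] <- m$overlap_len
  }
  list(
    merged = data.frame(id = ids[ok], seq = seqs[ok], qual = quals[ok],
                        overlap_len = ovls[ok], stringsAsFactors = FALSE),
    unmerged_ids = r1$id[!ok]
  )
}

merge_one <- function(s1, q1, s2, q2, trunc_qual, max_diffs, min_overlap) {
  t1 <- which(q1 <= trunc_qual)
  if (length(t1)) { s1 <- substr(s1, 1L, t1[1] - 1L); q1 <- q1[seq_len(t1[1] - 1L)] }
  t2 <- which(q2 <= trunc_qual)
  if (length(t2)) { s2 <- substr(s2, 1L, t2[1] - 1L); q2 <- q2[seq_len(t2[1] - 1L)] }
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (l1 < 1L || l2 < 1L) return(NULL)
  rc2 <- revcomp(s2)
  q2r <- rev(q2)
  for (ov in seq(min(l1, l2), min_overlap)) {
    if (ov < min_overlap) break
    a <- substr(s1, l1 - ov + 1L, l1)
    b <- substr(rc2, 1L, ov)
    if (max_diffs == 0L) {
      hit <- a == b
    } else {
      hit <- sum(utf8ToInt(a) != utf8ToInt(b)) <= max_diffs
    }
    if (hit) {
      qa <- q1[(l1 - ov + 1L):l1]
      qb <- q2r[seq_len(ov)]
      # with mismatches allowed the higher-quality base wins
      ovseq <- if (a == b) a else {
        av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
        paste(ifelse(qa >= qb, av, bv), collapse = "")
      }
      seq <- paste0(substr(s1, 1L, l1 - ov), ovseq, substr(rc2, ov + 1L, l2))
      qual <- c(q1[seq_len(l1 - ov)], pmax(qa, qb),
                q2r[seq(ov + 1L, length.out = l2 - ov)])
      return(list(seq = seq, qual = qual, overlap_len = ov))
    }
  }
  NULL
}

#' Glocal affine-gap alignment of a read to an amplicon reference
#'
#' Global in the read, local in the reference (reference end gaps are
#' free), optimal under affine gap scoring where a gap of length L costs
#' `gap_open + L * gap_extend`. Alignments are deterministic: score
#' ties prefer the smallest reference end position and indels are
#' left-normalised (shifted 5' while the flanking base repeats), so
#' indel inventories are reproducible.
#'
#' @param read read sequence (character) or a one-row data frame with
#'   `id` and `seq`.
#' @param amplicon reference sequence.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param id read identifier when `read` is a bare sequence.
#' @return An `aligned_read`: list with `id`, `seq`, `score`, `ops`
#'   (data frame `op` in match/mismatch/insertion/deletion, `len`,
#'   `ref_pos` 0-based; insertions use the position before which the
#'   bases are inserted), `ref_start`, `ref_end` (0-based half-open
#'   span) and `read_len`.
#' @export
align_glocal <- function(read, amplicon, match = 2, mismatch = -4,
                         gap_open = -6, gap_extend = -1, id = "read") {
  if (is.data.frame(read)) {
    id <- read$id[1]
    read <- read$seq[1]
  }
  if (is.na(read) || !nchar(read)) stop("empty read")
  read <- toupper(read)
  amplicon <- toupper(amplicon)
  if (grepl("[^ACGTN]", read) || grepl("[^ACGTN]", amplicon)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  n <- nchar(read)

  # fast path: an exact full-length substring match is always optimal;
  # take the leftmost occurrence (consistent with DP tie-breaking)
  hit <- regexpr(read, amplicon, fixed = TRUE)
  if (hit[1] != -1L) {
    s0 <- as.integer(hit[1]) - 1L
    return(structure(list(
      id = id, seq = read, score = n * match,
      ops = data.frame(op = "match", len = n, ref_pos = s0,
                       stringsAsFactors = FALSE),
      ref_start = s0, ref_end = s0 + n, read_len = n
    ), class = "aligned_read"))
  }

  raw <- .align_glocal_cpp(read, amplicon, match, mismatch,
                           gap_open, gap_extend)
  cols <- left_normalise(raw$op_kind, raw$op_refpos, read, amplicon)
  ops <- rle_ops(cols$kind, cols$refpos)
  consumed <- cols$kind %in% c(0L, 1L, 3L)
  if (any(consumed)) {
    ref_start <- min(cols$refpos[consumed])
    ref_end <- max(cols$refpos[consumed]) + 1L
  } else {
    ref_start <- ref_end <- cols$refpos[1]
  }
  structure(list(id = id, seq = read, score = raw$score, ops = ops,
                 ref_start = ref_start, ref_end = ref_end, read_len = n),
            class = "aligned_read")
}

# shift gap runs 5' while the flanking base repeats, so indel placement
# is unique regardless of traceback order
left_normalise <- function(kind, refpos, read, ref) {
  kind <- as.integer(kind)
  refpos <- as.integer(refpos)
  readpos <- integer(length(kind))      # 0-based read position per column
  rp <- 0L
  for (c in seq_along(kind)) {
    if (kind[c] != 3L) { readpos[c] <- rp; rp <- rp + 1L }
    else readpos[c] <- -1L
  }
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  fv <- strsplit(ref, "", fixed = TRUE)[[1]]

  repeat {
    moved <- FALSE
    c <- 1L
    while (c <= length(kind)) {
      if (kind[c] %in% c(2L, 3L)) {
        g <- kind[c]
        a <- c
        b <- a
        while (b < length(kind) && kind[b + 1L] == g) b <- b + 1L
        if (a > 1L && kind[a - 1L] %in% c(0L, 1L)) {
          shiftable <- if (g == 3L) {
            refpos[a] >= 1L && fv[refpos[a]] == fv[refpos[b] + 1L]
          } else {
            rv[readpos[b] + 1L] == rv[readpos[a - 1L] + 1L]
          }
          if (isTRUE(shiftable)) {
            # move the aligned column from before the run to after it
            prev_read <- readpos[a - 1L]
            if (g == 3L) {
              # deletion run covers refpos[a]..refpos[b]; shifts to
              # refpos[a]-1..refpos[b]-1; aligned column moves to refpos[b]
              new_ref <- refpos[b]
              kind[(a - 1L):(b - 1L)] <- 3L
              refpos[(a - 1L):(b - 1L)] <- refpos[a:b] - 1L
              readpos[(a - 1L):(b - 1L)] <- -1L
              st <- if (rv[prev_read + 1L] == fv[new_ref + 1L]) 0L else 1L
              kind[b] <- st
              refpos[b] <- new_ref
              readpos[b] <- prev_read
            } else {
              # insertion run: read bases readpos[a]..readpos[b] at point
              # refpos[a]; shift read bases back by one
              pt <- refpos[a] - 1L
              if (pt < 0L) { c <- b + 1L; next }
              kind[(a - 1L):(b - 1L)] <- 2L
              refpos[(a - 1L):(b - 1L)] <- pt
              readpos[(a - 1L):(b - 1L)] <- readpos[(a - 1L):(b - 1L)]
              # read positions stay consecutive: recompute below
              newread <- readpos[b]
              st <- if (rv[newread + 1L] == fv[pt + 1L]) 0L else 1L
              kind[b] <- st
              refpos[b] <- pt
              readpos[b] <- newread
              # fix read positions inside the shifted run
              readpos[(a - 1L):(b - 1L)] <- seq(prev_read,
                                                length.out = b - a + 1L)
            }
            moved <- TRUE
            next  # re-examine from the same index
          }
        }
        c <- b + 1L
      } else {
        c <- c + 1L
      }
    }
    if (!moved) break
  }
  list(kind = kind, refpos = refpos, readpos = readpos)
}

rle_ops <- function(kind, refpos) {
  labels <- c("match", "mismatch", "insertion", "deletion")
  if (!length(kind)) {
    return(data.frame(op = character(0), len = integer(0),
                      ref_pos = integer(0), stringsAsFactors = FALSE))
  }
  brk <- c(TRUE, kind[-1] != kind[-length(kind)])
  # split insertion runs at different insertion points
  brk <- brk | c(TRUE, kind[-1] == 2L & kind[-length(kind)] == 2L &
                   refpos[-1] != refpos[-length(refpos)])
  grp <- cumsum(brk)
  data.frame(
    op = labels[kind[brk] + 1L],
    len = as.integer(tabulate(grp)),
    ref_pos = refpos[brk],
    stringsAsFactors = FALSE
  )
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("aligned_read %s: %d nt, score %.1f, ref span [%d, %d)\n",
              x$id, x$read_len, x$score, x$ref_start, x$ref_end))
  cigar <- paste0(x$ops$len,
                  c(match = "=", mismatch = "X", insertion = "I",
                    deletion = "D")[x$ops$op], collapse = "")
  cat("  ops:", cigar, "\n")
  invisible(x)
}

#' Load read alignments from a SAM file
#'
#' Reconstructs per-read operation lists from CIGAR strings, splitting
#' `M` runs into match/mismatch against the target reference. Unmapped,
#' secondary and supplementary records are skipped; their counts are
#' returned as attributes. Soft-clipped bases are removed from the read
#' before conversion; hard clips are ignored.
#'
#' @param path SAM file.
#' @param targets list of [amplicon_target()] objects; records whose
#'   reference name matches no target are skipped and counted.
#' @return list of `aligned_read` objects with an additional `target`
#'   element naming the matched amplicon; attributes `n_unmapped`,
#'   `n_secondary`, `n_unmatched_ref`.
#' @export
load_alignments <- function(path, targets) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(names(targets))) {
    names(targets) <- vapply(targets, function(t) t$name, character(1))
  }
  lines <- readLines(path)
  out <- list()
  n_unmapped <- 0L; n_secondary <- 0L; n_unmatched <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nchar(line) || startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record at line ", ln)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) stop("malformed SAM record at line ", ln)
    if (bitwAnd(flag, 4L)) { n_unmapped <- n_unmapped + 1L; next }
    if (bitwAnd(flag, 256L) || bitwAnd(flag, 2048L)) {
      n_secondary <- n_secondary + 1L; next
    }
    tname <- f[3]
    if (!tname %in% names(targets)) { n_unmatched <- n_unmatched + 1L; next }
    target <- targets[[tname]]
    aln <- tryCatch(
      sam_to_aligned(f[1], pos - 1L, f[6], f[10], target$ref_seq),
      error = function(e) stop("malformed SAM record at line ", ln, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    aln$target <- tname
    out[[length(out) + 1L]] <- aln
  }
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_secondary") <- n_secondary
  attr(out, "n_unmatched_ref") <- n_unmatched
  out
}

sam_to_aligned <- function(id, pos0, cigar, seq, ref) {
  if (cigar == "*" || seq == "*") stop("record lacks CIGAR or sequence")
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L ||
      sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("unparseable CIGAR '", cigar, "'")
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  opsch <- sub("^[0-9]+", "", toks)

  kind <- integer(0); refpos <- integer(0)
  rpos <- pos0            # 0-based ref cursor
  qpos <- 1L              # 1-based read cursor
  keep_read <- character(0)
  for (k in seq_along(opsch)) {
    L <- lens[k]
    op <- opsch[k]
    if (op %in% c("M", "=", "X")) {
      rb <- substring(seq, qpos, qpos + L - 1L)
      fb <- substring(ref, rpos + 1L, rpos + L)
      rv <- strsplit(rb, "")[[1]]; fv <- strsplit(fb, "")[[1]]
      kind <- c(kind, ifelse(rv == fv, 0L, 1L))
      refpos <- c(refpos, rpos + seq_len(L) - 1L)
      keep_read <- c(keep_read, rv)
      rpos <- rpos + L; qpos <- qpos + L
    } else if (op == "I") {
      kind <- c(kind, rep(2L, L))
      refpos <- c(refpos, rep(rpos, L))
      keep_read <- c(keep_read, strsplit(substring(seq, qpos, qpos + L - 1L),
                                         "")[[1]])
      qpos <- qpos + L
    } else if (op %in% c("D", "N")) {
      kind <- c(kind, rep(3L, L))
      refpos <- c(refpos, rpos + seq_len(L) - 1L)
      rpos <- rpos + L
    } else if (op == "S") {
      qpos <- qpos + L
    } else if (op == "H") {
      # hard-clipped bases are absent from SEQ
    } else {
      stop("unsupported CIGAR op '", op, "'")
    }
  }
  ops <- rle_ops(kind, refpos)
  consumed <- kind %in% c(0L, 1L, 3L)
  structure(list(
    id = id, seq = paste(keep_read, collapse = ""), score = NA_real_,
    ops = ops,
    ref_start = if (any(consumed)) min(refpos[consumed]) else pos0,
    ref_end = if (any(consumed)) max(refpos[consumed]) + 1L else pos0,
    read_len = length(keep_read)
  ), class = "aligned_read")
}
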