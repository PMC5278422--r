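# Per-read classification of editing outcomes at an amplicon target and
# aggregation into the per-locus summaries used for allele-bias testing.

#' Define an amplicon target
#'
#' Everything needed to interpret one amplicon: the reference sequence,
#' the protospacer/PAM geometry, the diagnostic SNP distinguishing the
#' two parental alleles, and optional loxP knock-in and two-cut deletion
#' specifications. The PAM occupies the 3 nt immediately 3' of the
#' protospacer on the reference strand; the edit window defaults to the
#' protospacer plus PAM (23 nt).
#'
#' @param name locus label.
#' @param ref_seq amplicon reference sequence (protospacer on the
#'   forward strand of this sequence).
#' @param protospacer_span length-2 integer, 0-based half-open interval
#'   of the 20-nt protospacer on `ref_seq`.
#' @param edit_window optional length-2 interval an indel must overlap
#'   to count a read as edited; default protospacer plus PAM.
#' @param snp_offset 0-based position of the diagnostic SNP.
#' @param strain_a_base,strain_b_base the two parental bases (distinct).
#' @param strain_a_label,strain_b_label strain names used in outputs.
#' @param loxp optional list: `seq` (insert sequence containing the
#'   34-nt loxP site), `snp_offset`, `snp_base` (the loxP-specific SNP
#'   carried by the donor homology arm; defaults to `snp_offset` of the
#'   diagnostic SNP, and must differ from both strain bases when at
#'   that position).
#' @param deletion optional list for two-cut deletion assays:
#'   `junction_ref` (upstream segment fused to downstream segment),
#'   `junction_pos` (0-based fusion coordinate on `junction_ref`),
#'   `snp_offset` (diagnostic SNP position on `junction_ref`).
#' @param cut_offset 0-based position of the blunt cut on `ref_seq`;
#'   default 3 nt 5' of the PAM (between protospacer positions 17/18).
#' @return an `amplicon_target` object.
#' @export
amplicon_target <- function(name, ref_seq, protospacer_span,
                            edit_window = NULL, snp_offset,
                            strain_a_base, strain_b_base,
                            strain_a_label = "strain_a",
                            strain_b_label = "strain_b",
                            loxp = NULL, deletion = NULL,
                            cut_offset = NULL) {
  ref_seq <- toupper(ref_seq)
  if (grepl("[^ACGTN]", ref_seq)) stop("ref_seq has non-ACGTN characters")
  protospacer_span <- as.integer(protospacer_span)
  if (length(protospacer_span) != 2L ||
      diff(protospacer_span) != 20L ||
      protospacer_span[1] < 0L ||
      protospacer_span[2] + 3L > nchar(ref_seq)) {
    stop("protospacer_span must be a 20-nt interval with room for the PAM")
  }
  pam_span <- c(protospacer_span[2], protospacer_span[2] + 3L)
  pam <- substr(ref_seq, pam_span[1] + 2L, pam_span[2])
  if (pam != "GG") stop("reference PAM is not NGG at the stated protospacer")
  snp_offset <- as.integer(snp_offset)
  if (snp_offset < 0L || snp_offset >= nchar(ref_seq)) {
    stop("snp_offset outside ref_seq")
  }
  if (!is_base(strain_a_base) || !is_base(strain_b_base) ||
      strain_a_base == strain_b_base) {
    stop("strain bases must be distinct single nucleotides")
  }
  if (is.null(edit_window)) {
    edit_window <- c(protospacer_span[1], pam_span[2])
  }
  edit_window <- as.integer(edit_window)
  if (edit_window[2] <= edit_window[1] ||
      edit_window[1] >= protospacer_span[2] ||
      edit_window[2] <= protospacer_span[1]) {
    stop("edit_window must be a valid interval overlapping the protospacer")
  }
  if (!is.null(loxp)) {
    if (is.null(loxp$snp_offset)) loxp$snp_offset <- snp_offset
    loxp$snp_offset <- as.integer(loxp$snp_offset)
    if (is.null(loxp$seq) || !is_base(loxp$snp_base %||% "")) {
      stop("loxp spec needs seq and snp_base")
    }
    loxp$seq <- toupper(loxp$seq)
    if (loxp$snp_offset == snp_offset &&
        loxp$snp_base %in% c(strain_a_base, strain_b_base)) {
      stop("loxP-specific SNP base must differ from both strain bases")
    }
  }
  if (!is.null(deletion)) {
    if (is.null(deletion$junction_ref) || is.null(deletion$junction_pos)) {
      stop("deletion spec needs junction_ref and junction_pos")
    }
    deletion$junction_ref <- toupper(deletion$junction_ref)
    deletion$junction_pos <- as.integer(deletion$junction_pos)
    deletion$snp_offset <- as.integer(deletion$snp_offset %||% snp_offset)
  }
  if (is.null(cut_offset)) cut_offset <- protospacer_span[2] - 3L
  structure(list(
    name = name, ref_seq = ref_seq,
    protospacer_span = protospacer_span, pam_span = pam_span,
    edit_window = edit_window, snp_offset = snp_offset,
    strain_a_base = strain_a_base, strain_b_base = strain_b_base,
    strain_a_label = strain_a_label, strain_b_label = strain_b_label,
    loxp = loxp, deletion = deletion, cut_offset = as.integer(cut_offset)
  ), class = "amplicon_target")
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat(sprintf("amplicon_target '%s': %d nt reference\n", x$name,
              nchar(x$ref_seq)))
  cat(sprintf("  protospacer [%d, %d), PAM [%d, %d), edit window [%d, %d)\n",
              x$protospacer_span[1], x$protospacer_span[2],
              x$pam_span[1], x$pam_span[2],
              x$edit_window[1], x$edit_window[2]))
  cat(sprintf("  diagnostic SNP @%d: %s=%s, %s=%s\n", x$snp_offset,
              x$strain_a_label, x$strain_a_base,
              x$strain_b_label, x$strain_b_base))
  if (!is.null(x$loxp)) cat("  loxP knock-in configured\n")
  if (!is.null(x$deletion)) cat("  deletion junction configured\n")
  invisible(x)
}

# the read base aligned to a reference offset: list(kind, base) with
# kind in "base", "deleted", "uncovered"
read_base_at <- function(aln, ref_off) {
  if (ref_off < aln$ref_start || ref_off >= aln$ref_end) {
    return(list(kind = "uncovered", base = NA_character_))
  }
  qpos <- 0L
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[k]; L <- aln$ops$len[k]; p <- aln$ops$ref_pos[k]
    if (op %in% c("match", "mismatch")) {
      if (ref_off >= p && ref_off < p + L) {
        return(list(kind = "base",
                    base = substr(aln$seq, qpos + ref_off - p + 1L,
                                  qpos + ref_off - p + 1L)))
      }
      qpos <- qpos + L
    } else if (op == "insertion") {
      qpos <- qpos + L
    } else { # deletion
      if (ref_off >= p && ref_off < p + L) {
        return(list(kind = "deleted", base = NA_character_))
      }
    }
  }
  list(kind = "uncovered", base = NA_character_)
}

#' Assign an aligned read to a parental allele via the diagnostic SNP
#'
#' When a loxP knock-in is configured, the loxP-specific SNP is checked
#' first: a read carrying the donor base is recombination-derived and
#' cannot be attributed to either parental chromosome, so it is
#' indeterminate. A read whose diagnostic base is deleted, not covered,
#' or matches neither strain base (likely sequencing error) is also
#' indeterminate.
#'
#' @param aln an `aligned_read`.
#' @param target an [amplicon_target()].
#' @return one of `"strain_a"`, `"strain_b"`, `"indeterminate"`.
#' @export
assign_allele <- function(aln, target) {
  if (!is.null(target$loxp)) {
    lb <- read_base_at(aln, target$loxp$snp_offset)
    if (identical(lb$kind, "base") &&
        identical(lb$base, target$loxp$snp_base)) {
      return("indeterminate")
    }
  }
  sb <- read_base_at(aln, target$snp_offset)
  if (sb$kind != "base") return("indeterminate")
  if (sb$base == target$strain_a_base) return("strain_a")
  if (sb$base == target$strain_b_base) return("strain_b")
  "indeterminate"
}

#' Classify a read as edited from its indels over the target window
#'
#' A read is edited if at least one insertion or deletion overlaps the
#' edit window; substitutions never count. Deletions overlap the window
#' by interval intersection; an insertion point counts when it falls
#' inside the window or on either boundary.
#'
#' @param aln an `aligned_read` against `target$ref_seq`.
#' @param target an [amplicon_target()].
#' @return list with `edited` flag and `indels` data frame
#'   (`kind`, `len`, `ref_pos`; all indels on the read, window or not).
#' @export
classify_edit <- function(aln, target) {
  ws <- target$edit_window[1]; we <- target$edit_window[2]
  ops <- aln$ops
  ind <- ops[ops$op %in% c("insertion", "deletion"), , drop = FALSE]
  if (!nrow(ind)) {
    return(list(edited = FALSE,
                indels = data.frame(kind = character(0), len = integer(0),
                                    ref_pos = integer(0),
                                    stringsAsFactors = FALSE)))
  }
  in_window <- ifelse(
    ind$op == "deletion",
    ind$ref_pos < we & ind$ref_pos + ind$len > ws,
    ind$ref_pos >= ws & ind$ref_pos <= we
  )
  list(edited = any(in_window),
       indels = data.frame(kind = ind$op, len = ind$len,
                           ref_pos = ind$ref_pos, stringsAsFactors = FALSE))
}

#' Detect loxP integration by k-mer containment
#'
#' A read is loxP-positive if it contains any length-`k` substring of
#' the loxP sequence (default the canonical 34-mer, `k = 10`), searched
#' in forward orientation; set `both_strands = TRUE` to also search the
#' reverse complement of the loxP sequence.
#'
#' @param seqs character vector of read sequences.
#' @param loxp_seq the loxP (or donor) sequence.
#' @param k substring length.
#' @param both_strands also match the reverse complement.
#' @return logical vector, one flag per read.
#' @export
detect_loxp <- function(seqs, loxp_seq = LOXP_SEQ, k = 10,
                        both_strands = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (k > nchar(loxp_seq)) stop("k exceeds the loxP sequence length")
  queries <- toupper(loxp_seq)
  if (both_strands) queries <- c(queries, revcomp(queries))
  kmers <- unique(unlist(lapply(queries, function(q) {
    substring(q, seq_len(nchar(q) - k + 1L), k:nchar(q))
  })))
  hit <- rep(FALSE, length(seqs))
  for (km in kmers) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- grepl(km, seqs[todo], fixed = TRUE)
  }
  hit
}

#' Classify a read from a two-cut deletion assay
#'
#' Reads are aligned to the junction reference (upstream segment fused
#' to downstream segment). A read supports the deletion junction when
#' it aligns across the fusion coordinate with at least `min_side`
#' matched bases on each side; its allele is assigned from the junction
#' reference's diagnostic SNP.
#'
#' @param aln an `aligned_read` against the junction reference.
#' @param target an [amplicon_target()] with a `deletion` spec.
#' @param min_side minimum matched bases required on each side of the
#'   junction.
#' @return list with `junction` flag and `allele`.
#' @export
classify_deletion_read <- function(aln, target, min_side = 10) {
  if (is.null(target$deletion)) {
    stop("target '", target$name, "' has no deletion specification")
  }
  jp <- target$deletion$junction_pos
  m <- aln$ops[aln$ops$op == "match", , drop = FALSE]
  left <- 0L; right <- 0L
  if (nrow(m)) {
    s <- m$ref_pos; e <- m$ref_pos + m$len
    left <- sum(pmax(0L, pmin(e, jp) - s))
    right <- sum(pmax(0L, e - pmax(s, jp)))
  }
  junction <- left >= min_side && right >= min_side
  jt <- target
  jt$snp_offset <- target$deletion$snp_offset
  jt$loxp <- NULL
  allele <- if (junction) assign_allele(aln, jt) else "indeterminate"
  list(junction = junction, allele = allele)
}

#' Classify a set of aligned reads against a target
#'
#' Runs [assign_allele()], [classify_edit()], [detect_loxp()] (when a
#' loxP spec is configured) and [classify_deletion_read()] (when a
#' deletion spec is configured) over every read.
#'
#' @param alignments list of `aligned_read` objects.
#' @param target an [amplicon_target()].
#' @param loxp_k k-mer length for loxP detection.
#' @param min_side junction support threshold per side.
#' @return a `read_classifications` data frame with columns `id`,
#'   `allele`, `edited`, `loxp_positive`, `junction`; the full indel
#'   inventory is attached as attribute `indels` (one row per indel:
#'   `read_id`, `kind`, `len`, `ref_pos`).
#' @export
classify_reads <- function(alignments, target, loxp_k = 10, min_side = 10) {
  n <- length(alignments)
  id <- character(n); allele <- character(n)
  edited <- logical(n); junction <- rep(NA, n)
  inv <- vector("list", n)
  is_del <- !is.null(target$deletion)
  for (i in seq_len(n)) {
    aln <- alignments[[i]]
    id[i] <- aln$id
    if (is_del) {
      d <- classify_deletion_read(aln, target, min_side)
      junction[i] <- d$junction
      allele[i] <- d$allele
    } else {
      allele[i] <- assign_allele(aln, target)
    }
    ce <- classify_edit(aln, target)
    edited[i] <- ce$edited
    if (nrow(ce$indels)) {
      ce$indels$read_id <- aln$id
      inv[[i]] <- ce$indels
    }
  }
  loxp <- if (!is.null(target$loxp)) {
    detect_loxp(vapply(alignments, function(a) a$seq, character(1)),
                loxp_seq = target$loxp$seq, k = loxp_k)
  } else rep(FALSE, n)
  out <- data.frame(id = id, allele = allele, edited = edited,
                    loxp_positive = loxp, junction = as.logical(junction),
                    stringsAsFactors = FALSE)
  indels <- if (any(!vapply(inv, is.null, logical(1)))) {
    do.call(rbind, inv[!vapply(inv, is.null, logical(1))])
  } else {
    data.frame(kind = character(0), len = integer(0), ref_pos = integer(0),
               read_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(indels) <- NULL
  attr(out, "indels") <- indels
  class(out) <- c("read_classifications", "data.frame")
  out
}

#' Summarise read classifications for one locus
#'
#' Per allele class (strain A, strain B, indeterminate): total reads,
#' edited reads, loxP-positive reads and junction reads. Edited
#' percentages are computed per allele over that allele's strain-
#' specific reads; loxP percentages per strain over *total* mapped
#' reads; junction percentages per strain over strain-specific reads.
#' Percentages over zero reads are reported as `NA`.
#'
#' @param classifications a `read_classifications` data frame.
#' @param target the [amplicon_target()] the reads were classified
#'   against.
#' @return a `locus_summary` object.
#' @export
summarize_locus <- function(classifications, target) {
  if (!nrow(classifications)) {
    stop("no classified reads for locus '", target$name, "'")
  }
  cls <- c("strain_a", "strain_b", "indeterminate")
  total <- vapply(cls, function(k) sum(classifications$allele == k),
                  integer(1))
  edited <- vapply(cls, function(k)
    sum(classifications$edited & classifications$allele == k), integer(1))
  loxp <- vapply(cls, function(k)
    sum(classifications$loxp_positive & classifications$allele == k),
    integer(1))
  junc <- vapply(cls, function(k)
    sum(classifications$junction %in% TRUE & classifications$allele == k),
    integer(1))
  n_total <- nrow(classifications)
  stopifnot(sum(total) == n_total)   # conservation of the accounting
  pct <- function(num, den) {
    out <- 100 * num / den
    out[rep_len(den <= 0, length(out))] <- NA_real_
    out
  }
  indels <- attr(classifications, "indels")
  hist <- if (nrow(indels)) table(kind = indels$kind, len = indels$len)
          else table(kind = character(0), len = integer(0))
  structure(list(
    target = target$name,
    labels = c(strain_a = target$strain_a_label,
               strain_b = target$strain_b_label,
               indeterminate = "indeterminate"),
    total = total, edited = edited, loxp = loxp, junction = junc,
    n_total = n_total,
    edited_pct = pct(edited, total),
    loxp_pct = setNames(pct(loxp, n_total), cls),
    junction_pct = pct(junc, total),
    indel_hist = hist
  ), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("Locus '%s': %d reads\n", x$target, x$n_total))
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  df <- data.frame(
    class = unname(x$labels),
    total = x$total,
    edited = x$edited,
    `edited%` = fmt(x$edited_pct),
    loxP = x$loxp,
    `loxP%` = fmt(x$loxp_pct),
    junction = x$junction,
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Test allele bias in editing with a chi-squared test
#'
#' Builds the edited/unedited by strain-A/strain-B 2x2 table from a
#' locus summary and applies [chi_squared_2x2()]. Indeterminate reads
#' are excluded, as they cannot be attributed to a chromosome.
#'
#' @param summary a `locus_summary`.
#' @param yates apply the Yates continuity correction.
#' @return list with `table`, `statistic`, `p_value`, `df`.
#' @export
compare_alleles <- function(summary, yates = FALSE) {
  ta <- summary$total[["strain_a"]]; tb <- summary$total[["strain_b"]]
  if (ta == 0L || tb == 0L) {
    stop("an allele has zero reads; use fisher_exact_2x2 on raw counts")
  }
  ea <- summary$edited[["strain_a"]]; eb <- summary$edited[["strain_b"]]
  tab <- matrix(c(ea, eb, ta - ea, tb - eb), nrow = 2, byrow = TRUE,
                dimnames = list(c("edited", "unedited"),
                                unname(summary$labels[1:2])))
  res <- chi_squared_2x2(tab, yates = yates)
  c(list(table = tab), res)
}
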