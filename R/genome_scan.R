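# Genome-wide enumeration of candidate SpCas9 target sites and
# identification of sites discriminating two strains via SNVs.
#
# Coordinates are 0-based half-open throughout; reverse-strand sites are
# reported in forward coordinates with strand "-" and strand-oriented
# protospacer/PAM sequences.

#' Scan a genome for N20-NGG CRISPR/Cas9 target sites
#'
#' Every GG dinucleotide on either strand anchors a potential SpCas9
#' target: the 23-nt window consisting of a 20-nt protospacer, the PAM N
#' and the PAM GG. One site is emitted per GG anchor having at least
#' 21 nt of 5' flanking sequence on its strand; overlapping anchors (a
#' GGG run) yield independent sites.
#'
#' @param genome named character vector of sequences (or a
#'   `DNAStringSet`); alphabet `A,C,G,T,N`.
#' @param n_policy `"drop"` (default) removes sites whose 23-nt window
#'   contains an N (such guides are undesignable); `"keep"` retains
#'   them for counting conventions that ignore assembly gaps.
#' @param pam PAM motif; only `"NGG"` is supported (exposed so the
#'   restriction is explicit).
#' @return A `crispr_sites` data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open, `end - start == 23`), `strand`,
#'   `protospacer` (20 nt, 5'->3' on the site strand), `pam` (3 nt,
#'   `NGG`) and `score` (`NA` until scored), sorted by
#'   (chrom, start, strand).
#' @seealso [mark_strain_specific()], [score_sites()], [write_sites()]
#' @examples
#' scan_pam_sites(c(chr1 = paste0(strrep("A", 20), "AGG")))
#' @export
scan_pam_sites <- function(genome, n_policy = c("drop", "keep"), pam = "NGG") {
  n_policy <- match.arg(n_policy)
  if (!identical(toupper(pam), "NGG")) {
    stop("only the NGG PAM is supported")
  }
  genome <- as_genome(genome)

  one_chrom <- function(chrom, seq) {
    L <- nchar(seq)
    out <- list()
    if (L >= 23L) {
      # forward strand: GG anchors with >= 21 nt of 5' context
      g <- overlapping_positions(seq, "GG")
      g <- g[g >= 22L & g + 1L <= L]
      if (length(g)) {
        start <- g - 22L                      # 0-based window start
        out$fwd <- data.frame(
          chrom = chrom, start = start, end = start + 23L, strand = "+",
          protospacer = substring(seq, g - 21L, g - 2L),
          pam = substring(seq, g - 1L, g + 1L),
          score = NA_real_, stringsAsFactors = FALSE
        )
      }
      # reverse strand: CC anchors with >= 21 nt of 3' context
      cc <- overlapping_positions(seq, "CC")
      cc <- cc[cc + 22L <= L]
      if (length(cc)) {
        win <- substring(seq, cc, cc + 22L)
        rc <- revcomp(win)
        out$rev <- data.frame(
          chrom = chrom, start = cc - 1L, end = cc + 22L, strand = "-",
          protospacer = substring(rc, 1L, 20L),
          pam = substring(rc, 21L, 23L),
          score = NA_real_, stringsAsFactors = FALSE
        )
      }
    }
    if (!length(out)) return(empty_sites())
    do.call(rbind, out)
  }

  sites <- do.call(rbind, Map(one_chrom, names(genome), unname(genome)))
  if (is.null(sites) || !nrow(sites)) sites <- empty_sites()
  if (n_policy == "drop" && nrow(sites)) {
    keep <- !grepl("N", sites$protospacer, fixed = TRUE) &
      !grepl("N", sites$pam, fixed = TRUE)
    sites <- sites[keep, , drop = FALSE]
  }
  sites <- sites[order(sites$chrom, sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("crispr_sites", "data.frame")
  sites
}

# all (overlapping) 1-based start positions of a fixed pattern
overlapping_positions <- function(seq, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

empty_sites <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), protospacer = character(0),
             pam = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Score candidate sites with a pluggable scoring function
#'
#' Guide efficiency models vary; scoring is therefore pluggable. The
#' default scorer assigns every site 1.0 (all candidates pass), which
#' keeps downstream counting transparent; substitute any function
#' mapping a 23-nt window to `[0, 1]`.
#'
#' @param sites a `crispr_sites` data frame from [scan_pam_sites()].
#' @param scorer function taking a character vector of 23-nt windows
#'   (protospacer + PAM) and returning numeric scores in `[0, 1]`.
#' @return `sites` with the `score` column filled in.
#' @export
score_sites <- function(sites, scorer = scorer_uniform()) {
  if (!nrow(sites)) return(sites)
  windows <- paste0(sites$protospacer, sites$pam)
  s <- as.numeric(scorer(windows))
  if (length(s) != nrow(sites)) {
    stop("scorer must return one score per site")
  }
  if (anyNA(s) || any(s < 0 | s > 1)) {
    stop("scorer returned values outside [0, 1]")
  }
  sites$score <- s
  sites
}

#' @rdname score_sites
#' @param value constant score assigned by the uniform scorer.
#' @export
scorer_uniform <- function(value = 1.0) {
  force(value)
  function(windows) rep(value, length(windows))
}

#' Mark sites whose protospacer or PAM contains a strain-discriminating SNV
#'
#' A candidate site discriminates two strains when a biallelic SNV falls
#' inside its 20-nt protospacer or in either G of the PAM. The PAM N
#' position is excluded: N matches any base, so a variant there cannot
#' affect targeting. Offsets and PAM distances are computed in
#' site-strand orientation; `distance_from_pam` is 20 for the
#' protospacer position farthest from the PAM, 1 for the position
#' adjacent to it, and 0 for hits in the PAM GG.
#'
#' @param sites `crispr_sites` data frame.
#' @param variants data frame of biallelic SNVs with columns `chrom`,
#'   `pos` (0-based), `strain_a_base`, `strain_b_base` and optionally
#'   `strain_a_label`, `strain_b_label`. Non-SNV rows are dropped with a
#'   warning giving the count.
#' @return A `strain_specific_sites` data frame: the site columns plus
#'   `var_pos`, `strain_a_base`, `strain_b_base`, labels,
#'   `offset_in_window` (0..22, site strand), `distance_from_pam` and
#'   `in_pam`. One row per (site, variant) pair.
#' @export
mark_strain_specific <- function(sites, variants) {
  variants <- validate_variants(variants)
  if (!nrow(sites) || !nrow(variants)) return(empty_ss_sites(sites))

  out <- list()
  for (chrom in unique(sites$chrom)) {
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    if (!nrow(s) || !nrow(v)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(v$pos + 1L, v$pos + 1L),
      IRanges::IRanges(s$start + 1L, s$end)
    )
    if (!length(ov)) next
    si <- s[S4Vectors::subjectHits(ov), , drop = FALSE]
    vi <- v[S4Vectors::queryHits(ov), , drop = FALSE]
    offset <- ifelse(si$strand == "+",
                     vi$pos - si$start,
                     si$end - 1L - vi$pos)
    keep <- offset != 20L                      # PAM N is unconstrained
    if (!any(keep)) next
    si <- si[keep, , drop = FALSE]
    vi <- vi[keep, , drop = FALSE]
    offset <- offset[keep]
    in_pam <- offset >= 21L
    res <- si
    res$var_pos <- vi$pos
    res$strain_a_base <- vi$strain_a_base
    res$strain_b_base <- vi$strain_b_base
    res$strain_a_label <- vi$strain_a_label
    res$strain_b_label <- vi$strain_b_label
    res$offset_in_window <- as.integer(offset)
    res$distance_from_pam <- as.integer(ifelse(in_pam, 0L, 20L - offset))
    res$in_pam <- in_pam
    out[[chrom]] <- res
  }
  if (!length(out)) return(empty_ss_sites(sites))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand, res$var_pos), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("strain_specific_sites", "data.frame")
  res
}

validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "strain_a_base", "strain_b_base")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lack columns: ", paste(miss, collapse = ", "))
  if (is.null(variants$strain_a_label)) {
    variants$strain_a_label <- rep_len("strain_a", nrow(variants))
  }
  if (is.null(variants$strain_b_label)) {
    variants$strain_b_label <- rep_len("strain_b", nrow(variants))
  }
  ok <- is_base(variants$strain_a_base) & is_base(variants$strain_b_base) &
    variants$strain_a_base != variants$strain_b_base
  if (any(!ok)) {
    warning(sum(!ok), " variant(s) rejected (not biallelic SNVs)")
    variants <- variants[ok, , drop = FALSE]
  }
  variants
}

empty_ss_sites <- function(sites) {
  res <- cbind(
    empty_sites(),
    data.frame(var_pos = integer(0), strain_a_base = character(0),
               strain_b_base = character(0), strain_a_label = character(0),
               strain_b_label = character(0), offset_in_window = integer(0),
               distance_from_pam = integer(0), in_pam = logical(0),
               stringsAsFactors = FALSE)
  )
  class(res) <- c("strain_specific_sites", "data.frame")
  res
}

#' Annotate strain-specific sites against gene models
#'
#' Counts the unique coding exons and genes carrying strain-specific
#' sites, plus genes with at least one coding exon *flanked* by such
#' sites -- one site entirely 5' and one entirely 3' of the exon, both
#' within the gene span on the same chromosome (the geometry needed for
#' in-cis excision of an exon).
#'
#' A site hits an exon or gene when its 23-nt window overlaps the
#' interval; exons are deduplicated by coordinates across genes.
#'
#' @param ss_sites `strain_specific_sites` data frame.
#' @param genes gene models as a data frame of exons with columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open)
#'   and `coding` (logical); every gene must have at least one exon.
#' @return An `annotation_summary` list with `exon_hit_count`,
#'   `gene_hit_count` (coding-exon level), `gene_any_count` (exonic or
#'   intronic) and `gene_flanking_count`, plus the totals scanned.
#' @export
annotate_sites <- function(ss_sites, genes) {
  genes <- validate_genes(genes)
  gene_ids <- unique(genes$gene_id)
  coding <- genes[genes$coding, , drop = FALSE]
  # unique coding exons by coordinates
  exon_key <- unique(coding[, c("chrom", "start", "end")])

  span <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))

  exon_hit <- logical(nrow(exon_key))
  gene_codexon_hit <- logical(nrow(span))
  gene_any_hit <- logical(nrow(span))
  gene_flank <- logical(nrow(span))

  if (nrow(ss_sites)) {
    for (chrom in unique(ss_sites$chrom)) {
      s <- ss_sites[ss_sites$chrom == chrom, , drop = FALSE]
      sr <- IRanges::IRanges(s$start + 1L, s$end)
      ek <- which(exon_key$chrom == chrom)
      if (length(ek)) {
        er <- IRanges::IRanges(exon_key$start[ek] + 1L, exon_key$end[ek])
        exon_hit[ek] <- exon_hit[ek] |
          IRanges::overlapsAny(er, sr)
      }
      gk <- which(span$chrom == chrom)
      if (length(gk)) {
        gr <- IRanges::IRanges(span$start[gk] + 1L, span$end[gk])
        gene_any_hit[gk] <- gene_any_hit[gk] | IRanges::overlapsAny(gr, sr)
        for (i in gk) {
          gid <- span$gene_id[i]
          gs <- span$start[i]; ge <- span$end[i]
          within <- s$start >= gs & s$end <= ge
          cod <- coding[coding$gene_id == gid & coding$chrom == chrom, ,
                        drop = FALSE]
          if (nrow(cod)) {
            cr <- IRanges::IRanges(cod$start + 1L, cod$end)
            gene_codexon_hit[i] <- gene_codexon_hit[i] ||
              any(IRanges::overlapsAny(cr, sr))
            if (any(within)) {
              sw <- s[within, , drop = FALSE]
              gene_flank[i] <- gene_flank[i] || any(
                vapply(seq_len(nrow(cod)), function(k) {
                  any(sw$end <= cod$start[k]) && any(sw$start >= cod$end[k])
                }, logical(1))
              )
            }
          }
        }
      }
    }
  }

  out <- list(
    exon_hit_count = sum(exon_hit),
    gene_hit_count = sum(gene_codexon_hit),
    gene_any_count = sum(gene_any_hit),
    gene_flanking_count = sum(gene_flank),
    n_genes = length(gene_ids),
    n_coding_exons = nrow(exon_key)
  )
  class(out) <- "annotation_summary"
  out
}

validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "start", "end", "coding")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene models lack columns: ", paste(miss, collapse = ", "))
  if (!nrow(genes)) stop("gene models contain no exons")
  if (any(genes$end <= genes$start)) stop("exon with non-positive width")
  genes
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Strain-specific site annotation\n")
  cat(sprintf("  coding exons hit:        %d / %d\n",
              x$exon_hit_count, x$n_coding_exons))
  cat(sprintf("  genes hit (coding exon): %d / %d\n",
              x$gene_hit_count, x$n_genes))
  cat(sprintf("  genes hit (any):         %d / %d\n",
              x$gene_any_count, x$n_genes))
  cat(sprintf("  genes with flanked exon: %d / %d\n",
              x$gene_flanking_count, x$n_genes))
  invisible(x)
}
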