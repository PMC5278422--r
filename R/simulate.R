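# Synthetic-data generators. These emulate the experimental designs the
# toolkit quantifies: a diploid locus with a heterozygous diagnostic SNP
# inside a CRISPR target, per-allele indel rates at the cut site, loxP
# knock-ins carrying a donor-specific SNP, deletion-junction amplicons,
# and uniform substitution sequencing error. Every generator is
# reproducible under a fixed seed and returns a ground-truth manifest.

#' Simulate a random genome sequence
#'
#' @param length sequence length (>= 1).
#' @param gc_fraction expected G+C fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param name sequence name.
#' @return named character vector of length one (a one-contig genome).
#' @export
simulate_genome <- function(length, gc_fraction = 0.4, seed = 1L,
                            name = "chrS") {
  if (length < 1L) stop("length must be >= 1")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction outside [0, 1]")
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = prob),
    collapse = ""))
  setNames(seq, name)
}

#' Simulate biallelic strain variants along a genome
#'
#' Each position carries a variant independently with probability
#' `density`; strain A keeps the reference base and strain B receives a
#' different base drawn uniformly.
#'
#' @param genome named character vector of sequences.
#' @param density per-base variant probability in `[0, 1]`.
#' @param seed integer seed.
#' @param labels length-2 strain labels.
#' @return variant data frame as consumed by [mark_strain_specific()],
#'   positions 0-based, unique and sorted.
#' @export
simulate_strain_variants <- function(genome, density, seed = 1L,
                                     labels = c("strain_a", "strain_b")) {
  if (density < 0 || density > 1) stop("density outside [0, 1]")
  genome <- as_genome(genome)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- lapply(names(genome), function(chrom) {
      seq <- genome[[chrom]]
      L <- nchar(seq)
      pos <- which(runif(L) < density)
      if (!length(pos)) return(NULL)
      ref <- substring(seq, pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1), USE.NAMES = FALSE)
      keep <- ref %in% bases               # skip N positions
      data.frame(chrom = chrom, pos = pos[keep] - 1L,
                 strain_a_base = ref[keep], strain_b_base = alt[keep],
                 strain_a_label = labels[1], strain_b_label = labels[2],
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(chrom = character(0), pos = integer(0),
                        strain_a_base = character(0),
                        strain_b_base = character(0),
                        strain_a_label = character(0),
                        strain_b_label = character(0),
                        stringsAsFactors = FALSE)
    }
    rownames(res) <- NULL
    res
  })
}

#' Simulate gene models on a genome
#'
#' Places non-overlapping genes of `n_exons` coding exons each, with
#' fixed exon and intron sizes scaled to fit, purely as an annotation
#' substrate for [annotate_sites()].
#'
#' @param genome named character vector.
#' @param n_genes number of genes per sequence.
#' @param n_exons exons per gene.
#' @param exon_len,intron_len exon and intron lengths (nt).
#' @param seed integer seed (gene starts are jittered).
#' @return exon data frame as consumed by [annotate_sites()].
#' @export
simulate_gene_models <- function(genome, n_genes = 5, n_exons = 3,
                                 exon_len = 60, intron_len = 120,
                                 seed = 1L) {
  genome <- as_genome(genome)
  gene_len <- n_exons * exon_len + (n_exons - 1L) * intron_len
  with_seed(seed, {
    out <- lapply(names(genome), function(chrom) {
      L <- nchar(genome[[chrom]])
      slot <- L %/% n_genes
      if (slot <= gene_len) stop("genome too short for requested genes")
      starts <- (seq_len(n_genes) - 1L) * slot +
        sample.int(slot - gene_len, n_genes, replace = TRUE) - 1L
      do.call(rbind, lapply(seq_len(n_genes), function(g) {
        es <- starts[g] + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
        data.frame(gene_id = sprintf("%s_g%02d", chrom, g), chrom = chrom,
                   strand = "+", start = es, end = es + exon_len,
                   coding = TRUE, stringsAsFactors = FALSE)
      }))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulation settings for amplicon read generation
#'
#' @param seed integer seed.
#' @param n_read_pairs number of read pairs to emit.
#' @param allele_ratio probability a read pair derives from strain A.
#' @param edit_rate_a,edit_rate_b per-allele indel probability.
#' @param loxp_rate probability of a loxP knock-in (mutually exclusive
#'   with a plain indel; requires a `loxp` spec on the target).
#' @param loxp_snp_conversion probability that a knock-in read also
#'   incorporates the donor-specific SNP (HDR conversion tracts are
#'   partial, so some knock-in reads keep the parental base and remain
#'   strain-assignable).
#' @param indel_geom_p geometric parameter for indel lengths
#'   (length = 1 + Geom(p), truncated at `indel_max`).
#' @param indel_max maximum indel length.
#' @param error_rate per-base substitution sequencing error rate.
#' @param read_length read length (both mates).
#' @param base_quality constant Phred quality assigned to all bases.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_read_pairs = 1000L,
                              allele_ratio = 0.5, edit_rate_a = 0.30,
                              edit_rate_b = 0.05, loxp_rate = 0,
                              loxp_snp_conversion = 0.5,
                              indel_geom_p = 0.5, indel_max = 20L,
                              error_rate = 0.001, read_length = 130L,
                              base_quality = 37L) {
  probs <- c(allele_ratio = allele_ratio, edit_rate_a = edit_rate_a,
             edit_rate_b = edit_rate_b, loxp_rate = loxp_rate,
             loxp_snp_conversion = loxp_snp_conversion,
             indel_geom_p = indel_geom_p, error_rate = error_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop(names(probs)[bad][1], " outside [0, 1]")
  if (n_read_pairs < 0L) stop("n_read_pairs must be >= 0")
  if (read_length < 1L || indel_max < 1L) stop("lengths must be positive")
  structure(list(seed = as.integer(seed),
                 n_read_pairs = as.integer(n_read_pairs),
                 allele_ratio = allele_ratio, edit_rate_a = edit_rate_a,
                 edit_rate_b = edit_rate_b, loxp_rate = loxp_rate,
                 loxp_snp_conversion = loxp_snp_conversion,
                 indel_geom_p = indel_geom_p,
                 indel_max = as.integer(indel_max),
                 error_rate = error_rate,
                 read_length = as.integer(read_length),
                 base_quality = as.integer(base_quality)),
            class = "sim_config")
}

#' Simulate paired amplicon reads with planted edits
#'
#' Each read pair derives from strain A with probability
#' `allele_ratio`. On the chosen allele, with probability `loxp_rate`
#' the donor outcome is planted (the loxP sequence inserted at the cut
#' site and the loxP-specific SNP written into the homology-arm
#' position); otherwise an indel is planted at the cut site with the
#' allele's edit rate (insertion or deletion with equal probability,
#' geometric length). When the target carries a `deletion` spec, reads
#' are drawn from the junction reference instead and all carry the
#' junction. Substitution errors are added per base; mates read the two
#' fragment ends, overlapping in the middle.
#'
#' @param target an [amplicon_target()].
#' @param config a [simulation_config()].
#' @return list with `r1`, `r2` (FASTQ data frames) and `manifest`
#'   (data frame `id`, `allele`, `edit_kind`, `edit_len`, `edit_pos`,
#'   `loxp`, `junction`).
#' @export
simulate_edited_amplicons <- function(target, config) {
  stopifnot(inherits(target, "amplicon_target"),
            inherits(config, "sim_config"))
  junction_mode <- !is.null(target$deletion)
  ref <- if (junction_mode) target$deletion$junction_ref else target$ref_seq
  snp <- if (junction_mode) target$deletion$snp_offset else target$snp_offset
  cut <- if (junction_mode) target$deletion$junction_pos else target$cut_offset
  RL <- config$read_length

  max_growth <- config$indel_max
  if (config$loxp_rate > 0) {
    if (is.null(target$loxp)) stop("loxp_rate > 0 but target has no loxp spec")
    max_growth <- max(max_growth, nchar(target$loxp$seq))
  }
  if (2L * RL < nchar(ref) + max_growth + 50L || RL <= snp) {
    stop("read_length too short to cover the diagnostic SNP and merge")
  }

  set_base <- function(s, off, b) {
    paste0(substr(s, 1L, off), b, substr(s, off + 2L, nchar(s)))
  }
  tmpl <- list(
    strain_a = set_base(ref, snp, target$strain_a_base),
    strain_b = set_base(ref, snp, target$strain_b_base)
  )
  bases <- c("A", "C", "G", "T")
  n <- config$n_read_pairs
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  manifest0 <- data.frame(id = character(0), allele = character(0),
                          edit_kind = character(0), edit_len = integer(0),
                          edit_pos = integer(0), loxp = logical(0),
                          junction = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(r1 = empty, r2 = empty, manifest = manifest0))

  with_seed(config$seed, {
    allele <- ifelse(runif(n) < config$allele_ratio, "strain_a", "strain_b")
    u_event <- runif(n)
    ids <- sprintf("read%06d", seq_len(n))
    seqs1 <- character(n); seqs2 <- character(n)
    kind <- rep("none", n); elen <- rep(NA_integer_, n)
    epos <- rep(NA_integer_, n); loxp <- logical(n)

    for (i in seq_len(n)) {
      frag <- tmpl[[allele[i]]]
      rate <- if (allele[i] == "strain_a") config$edit_rate_a
              else config$edit_rate_b
      if (config$loxp_rate > 0 && u_event[i] < config$loxp_rate) {
        if (runif(1) < config$loxp_snp_conversion) {
          frag <- set_base(frag, target$loxp$snp_offset, target$loxp$snp_base)
        }
        frag <- paste0(substr(frag, 1L, cut), target$loxp$seq,
                       substr(frag, cut + 1L, nchar(frag)))
        kind[i] <- "loxp"; loxp[i] <- TRUE
        elen[i] <- nchar(target$loxp$seq); epos[i] <- cut
      } else if (u_event[i] < config$loxp_rate + rate * (1 - config$loxp_rate)) {
        L <- min(1L + rgeom(1L, config$indel_geom_p), config$indel_max)
        if (runif(1) < 0.5 && cut + L < nchar(frag)) {
          frag <- paste0(substr(frag, 1L, cut),
                         substr(frag, cut + L + 1L, nchar(frag)))
          kind[i] <- "deletion"
        } else {
          ins <- paste(sample(bases, L, replace = TRUE), collapse = "")
          frag <- paste0(substr(frag, 1L, cut), ins,
                         substr(frag, cut + 1L, nchar(frag)))
          kind[i] <- "insertion"
        }
        elen[i] <- L; epos[i] <- cut
      }
      FL <- nchar(frag)
      s1 <- substr(frag, 1L, min(RL, FL))
      s2 <- revcomp(substr(frag, max(1L, FL - RL + 1L), FL))
      seqs1[i] <- add_errors(s1, config$error_rate, bases)
      seqs2[i] <- add_errors(s2, config$error_rate, bases)
    }
    qual1 <- vapply(nchar(seqs1), function(L)
      strrep(intToUtf8(config$base_quality + 33L), L), character(1))
    qual2 <- vapply(nchar(seqs2), function(L)
      strrep(intToUtf8(config$base_quality + 33L), L), character(1))
    list(
      r1 = data.frame(id = ids, seq = seqs1, qual = qual1,
                      stringsAsFactors = FALSE),
      r2 = data.frame(id = ids, seq = seqs2, qual = qual2,
                      stringsAsFactors = FALSE),
      manifest = data.frame(id = ids, allele = allele, edit_kind = kind,
                            edit_len = elen, edit_pos = epos, loxp = loxp,
                            junction = junction_mode,
                            stringsAsFactors = FALSE)
    )
  })
}

add_errors <- function(seq, rate, bases) {
  if (rate <= 0) return(seq)
  L <- nchar(seq)
  k <- stats::rbinom(1L, L, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(L, k)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1L),
                   character(1), USE.NAMES = FALSE)
  paste(v, collapse = "")
}

#' Construct a synthetic amplicon target
#'
#' Builds a random amplicon with an embedded protospacer + NGG PAM and
#' a heterozygous diagnostic SNP inside the protospacer, mirroring the
#' geometry of a strain-discriminating locus. Optionally attaches a
#' loxP knock-in spec (donor-specific third base at the diagnostic
#' position) or a two-cut deletion junction reference.
#'
#' @param seed integer seed.
#' @param ref_len amplicon length.
#' @param proto_start 0-based protospacer start.
#' @param snp_in_proto 0-based SNP offset within the protospacer.
#' @param loxp attach a loxP spec.
#' @param deletion attach a deletion-junction spec (second cut
#'   `partner_gap` nt downstream of the amplicon end).
#' @param partner_gap distance from the first cut to the second cut.
#' @param name target name.
#' @return an [amplicon_target()].
#' @export
synthetic_target <- function(seed = 1L, ref_len = 170L, proto_start = 60L,
                             snp_in_proto = 9L, loxp = FALSE,
                             deletion = FALSE, partner_gap = 400L,
                             name = "locus1") {
  stopifnot(proto_start + 23L <= ref_len, snp_in_proto >= 0L,
            snp_in_proto < 20L)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    v <- sample(bases, ref_len, replace = TRUE)
    v[proto_start + 22L] <- "G"          # PAM GG
    v[proto_start + 23L] <- "G"
    ref <- paste(v, collapse = "")
    snp_offset <- proto_start + snp_in_proto
    a <- v[snp_offset + 1L]
    b <- sample(setdiff(bases, a), 1L)
    loxp_spec <- NULL
    if (loxp) {
      loxp_spec <- list(seq = LOXP_SEQ, snp_offset = snp_offset,
                        snp_base = sample(setdiff(bases, c(a, b)), 1L))
    }
    del_spec <- NULL
    if (deletion) {
      cut <- proto_start + 17L
      down <- paste(sample(bases, 80L, replace = TRUE), collapse = "")
      junction_ref <- paste0(substr(ref, 1L, cut), down)
      del_spec <- list(junction_ref = junction_ref, junction_pos = cut,
                       snp_offset = snp_offset)
    }
    amplicon_target(name = name, ref_seq = ref,
                    protospacer_span = c(proto_start, proto_start + 20L),
                    snp_offset = snp_offset, strain_a_base = a,
                    strain_b_base = b, strain_a_label = "strainA",
                    strain_b_label = "strainB", loxp = loxp_spec,
                    deletion = del_spec)
  })
}
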