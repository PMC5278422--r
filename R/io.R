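# Readers and writers for the standard formats the toolkit touches.
# Genome FASTA goes through Biostrings; GFF3/BED12 gene models through
# rtracklayer; VCF through vcfR (all optional inputs also accept plain
# TSV so small fixtures stay human-readable).

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("FASTA contains no sequences: ", path)
  # keep only the first word of each FASTA header
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Read strain variants from VCF or TSV
#'
#' TSV input has 4+ columns: chrom, pos (1-based), strain A base,
#' strain B base, with optional 5th/6th label columns. VCF input uses
#' REF as the strain A base and ALT as the strain B base; non-biallelic
#' or non-SNV records are dropped with a warning count.
#'
#' @param path variant file (`.vcf`/`.vcf.gz` or TSV).
#' @param strain_labels length-2 character, labels for the two strains.
#' @return data frame with columns `chrom`, `pos` (0-based),
#'   `strain_a_base`, `strain_b_base`, `strain_a_label`, `strain_b_label`.
#' @export
read_strain_variants <- function(path, strain_labels = c("strain_a", "strain_b")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    out <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS) - 1L,
                      strain_a_base = toupper(fix$REF),
                      strain_b_base = toupper(fix$ALT),
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 4L) stop("variant TSV needs >= 4 columns")
    out <- data.frame(chrom = as.character(tab[[1]]),
                      pos = as.integer(tab[[2]]) - 1L,
                      strain_a_base = toupper(tab[[3]]),
                      strain_b_base = toupper(tab[[4]]),
                      stringsAsFactors = FALSE)
    if (ncol(tab) >= 6L) {
      strain_labels <- c(as.character(tab[[5]][1]), as.character(tab[[6]][1]))
    }
  }
  out$strain_a_label <- strain_labels[1]
  out$strain_b_label <- strain_labels[2]
  validate_variants(out)
}

#' Read gene models from GFF3, BED12 or TSV
#'
#' GFF3 exon/CDS features and BED12 blocks are converted to the internal
#' exon table; a plain TSV with columns `gene_id`, `chrom`, `strand`,
#' `start`, `end`, `coding` (0-based half-open) is accepted directly.
#'
#' @param path gene model file.
#' @return exon data frame as used by [annotate_sites()].
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.(gff3?|gtf)$", lower)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    feat <- tolower(as.character(gr$type))
    keep <- feat %in% c("exon", "cds")
    gr <- gr[keep]
    feat <- feat[keep]
    if (!length(gr)) stop("no exon/CDS features in ", path)
    gid <- as.character(gr$gene_id %||% gr$Parent %||% gr$ID)
    genes <- data.frame(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      coding = feat == "cds",
      stringsAsFactors = FALSE
    )
    # genes annotated only with exons: treat exons as coding
    has_cds <- tapply(genes$coding, genes$gene_id, any)
    genes$coding[!has_cds[genes$gene_id]] <- TRUE
  } else if (grepl("\\.bed$", lower)) {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 12L) stop("BED gene models must be BED12")
    genes <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      n <- as.integer(tab[i, 10])
      sizes <- as.integer(strsplit(as.character(tab[i, 11]), ",")[[1]])[seq_len(n)]
      offs <- as.integer(strsplit(as.character(tab[i, 12]), ",")[[1]])[seq_len(n)]
      st <- as.integer(tab[i, 2]) + offs
      data.frame(gene_id = as.character(tab[i, 4]),
                 chrom = as.character(tab[i, 1]),
                 strand = as.character(tab[i, 6]),
                 start = st, end = st + sizes, coding = TRUE,
                 stringsAsFactors = FALSE)
    }))
  } else {
    genes <- read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    genes$coding <- as.logical(genes$coding)
  }
  validate_genes(genes)
}

#' Write candidate sites as BED6
#'
#' Columns: chrom, start, end, name (protospacer+PAM), score (site score
#' x 1000, rounded; 0 when unscored), strand. 0-based half-open.
#'
#' @param sites `crispr_sites` or `strain_specific_sites` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  score <- ifelse(is.na(sites$score), 0, round(sites$score * 1000))
  bed <- data.frame(sites$chrom, sites$start, sites$end,
                    paste0(sites$protospacer, sites$pam),
                    as.integer(score), sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site file written by [write_sites()]
#'
#' @param path BED file.
#' @return `crispr_sites` data frame (scores rescaled to `[0,1]`).
#' @export
read_sites <- function(path) {
  if (file.size(path) == 0) return(structure(empty_sites(),
    class = c("crispr_sites", "data.frame")))
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  sites <- data.frame(chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]),
                      end = as.integer(tab[[3]]),
                      strand = as.character(tab[[6]]),
                      protospacer = substring(tab[[4]], 1L, 20L),
                      pam = substring(tab[[4]], 21L, 23L),
                      score = as.numeric(tab[[5]]) / 1000,
                      stringsAsFactors = FALSE)
  class(sites) <- c("crispr_sites", "data.frame")
  sites
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  n <- length(lines) %/% 4L
  if (!n) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n)
  id <- sub("^@", "", sub("\\s.*$", "", lines[4L * idx - 3L]))
  seq <- toupper(lines[4L * idx - 2L])
  qual <- lines[4L * idx]
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence/quality length mismatch in ", path)
  }
  # validate encoding on the extremes only (cheap full check)
  rng <- range(utf8ToInt(paste(qual, collapse = "")))
  if (length(qual) && (rng[1] < 33L || rng[2] > 95L)) {
    stop("quality strings are not Phred+33 encoded in ", path)
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), path)
  invisible(path)
}

#' Read a target-definition sheet
#'
#' Tab-separated, one row per amplicon target, with header. Required
#' columns: `name`, `ref_seq`, `proto_start`, `proto_end` (0-based
#' half-open protospacer interval), `snp_offset`, `strain_a_base`,
#' `strain_b_base`. Optional: `strain_a_label`, `strain_b_label`,
#' `window_start`, `window_end`, `loxp_seq`, `loxp_snp_offset`,
#' `loxp_snp_base`, `junction_ref`, `junction_pos`,
#' `junction_snp_offset` (empty/NA when unused).
#'
#' @param path TSV file.
#' @return list of [amplicon_target()] objects, named by target.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # colClasses: a lone "T" base column must stay character, not logical
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  need <- c("name", "ref_seq", "proto_start", "proto_end", "snp_offset",
            "strain_a_base", "strain_b_base")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("target sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  get_opt <- function(row, col) {
    if (!col %in% names(tab)) return(NULL)
    v <- row[[col]]
    if (is.na(v) || identical(v, "")) NULL else v
  }
  opt_int <- function(row, col) {
    v <- get_opt(row, col)
    if (is.null(v)) NULL else as.integer(v)
  }
  targets <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, , drop = FALSE]
    loxp <- NULL
    if (!is.null(get_opt(row, "loxp_seq"))) {
      loxp <- list(seq = get_opt(row, "loxp_seq"),
                   snp_offset = opt_int(row, "loxp_snp_offset"),
                   snp_base = get_opt(row, "loxp_snp_base"))
    }
    deletion <- NULL
    if (!is.null(get_opt(row, "junction_ref"))) {
      deletion <- list(junction_ref = get_opt(row, "junction_ref"),
                       junction_pos = opt_int(row, "junction_pos"),
                       snp_offset = opt_int(row, "junction_snp_offset"))
    }
    ws <- get_opt(row, "window_start")
    amplicon_target(
      name = row$name, ref_seq = row$ref_seq,
      protospacer_span = c(row$proto_start, row$proto_end),
      edit_window = if (is.null(ws)) NULL else
        c(as.integer(ws), as.integer(get_opt(row, "window_end"))),
      snp_offset = row$snp_offset,
      strain_a_base = row$strain_a_base, strain_b_base = row$strain_b_base,
      strain_a_label = get_opt(row, "strain_a_label") %||% "strain_a",
      strain_b_label = get_opt(row, "strain_b_label") %||% "strain_b",
      loxp = loxp, deletion = deletion
    )
  })
  names(targets) <- tab$name
  targets
}
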