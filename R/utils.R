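# Shared helpers: sequence handling, seeded evaluation, validation.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `A,C,G,T,N`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Evaluate code under a fixed RNG seed, restoring global RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Normalise a genome to a named character vector of uppercase sequences.
# Accepts: named character vector, single unnamed string, or a
# Biostrings::DNAStringSet.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (!is.character(genome)) {
    stop("genome must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(genome))) {
    if (length(genome) == 1L) names(genome) <- "seq1"
    else stop("multi-sequence genome must be named")
  }
  genome <- toupper(genome)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop("sequence '", names(genome)[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  }
  genome
}

# single-base check used by variant validation
is_base <- function(x) {
  is.character(x) & nchar(x) == 1L & x %in% c("A", "C", "G", "T")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# decode a Phred+33 quality string into integer scores
decode_qual <- function(qual) {
  q <- utf8ToInt(qual) - 33L
  if (length(q) && (min(q) < 0L || max(q) > 62L)) {
    stop("quality string is not Phred+33 encoded")
  }
  q
}

encode_qual <- function(q) intToUtf8(as.integer(q) + 33L)

pkg_header <- function(params) {
  paste0("# crisprAllele ",
         as.character(utils::packageVersion("crisprAllele")),
         " | ", params)
}
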