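#' @useDynLib srnamine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname revcomp
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Round half away from zero to `digits` decimals, the presentation rule used
# for percentages (base round() goes half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Dinucleotide-preserving shuffle (swap-based), used for decoy/negative
# sequence generation. Operates on a single sequence.
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 4) return(seq)
  # Altschul-Erickson style via random Eulerian walk is overkill here; a
  # doublet-swap shuffle preserves dinucleotide counts approximately and is
  # sufficient for negatives.
  for (it in seq_len(4L * n)) {
    idx <- sample.int(n - 2L, 2L)
    i <- idx[1]; j <- idx[2]
    if (abs(i - j) < 2L) next
    if (ch[i] == ch[j] && ch[i + 1L] != ch[j + 1L]) {
      tmp <- ch[i + 1L]; ch[i + 1L] <- ch[j + 1L]; ch[j + 1L] <- tmp
    }
  }
  paste(ch, collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
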