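# RNA secondary structure: built-in pair-scored folder, dot-bracket parsing,
# helix decomposition, read-in-stem overlap classification and hairpin
# features. The folder is a Nussinov-style dynamic program over pair scores
# (GC > AU > GU), a deliberate stand-in for a thermodynamic folder: its score
# is an "energy proxy" (more negative = more stable), never kcal/mol.
# Externally computed dot-bracket + free-energy input is the faithful path
# (see read_vienna()).

#' Construct a secondary-structure object
#'
#' @param sequence nucleotide sequence; shown as RNA (T converted to U).
#' @param dot_bracket balanced dot-bracket string of the same length.
#' @param pairs two-column integer matrix of base pairs, 1-based, i < j.
#' @param energy_score stability score; more negative is more stable. The
#'   built-in folder fills in a pair-score proxy, [read_vienna()] keeps an
#'   externally supplied free energy.
#' @return an object of class `secondary_structure`.
#' @export
secondary_structure <- function(sequence, dot_bracket, pairs, energy_score = 0) {
  stopifnot(nchar(sequence) == nchar(dot_bracket))
  structure(
    list(sequence = dna_to_rna(toupper(sequence)), dot_bracket = dot_bracket,
         pairs = pairs, energy_score = energy_score),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: %d nt, %d pairs, energy proxy %.2f\n",
              nchar(x$sequence), nrow(x$pairs), x$energy_score))
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Fold a sequence with the built-in pair-scored dynamic program
#'
#' Finds the maximum-score pseudoknot-free structure under per-pair scores
#' (default GC = 3, AU = 2, GU = 1, reported negated as an energy proxy) with
#' a minimum hairpin loop length. Tie-breaking is deterministic: a base pairs
#' rather than staying unpaired on equal score, and with its smallest-index
#' admissible partner.
#'
#' @param sequence DNA or RNA sequence (length >= `min_loop + 2` to form any
#'   pair; shorter input folds to the open chain).
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @param scoring named numeric vector of pair scores, names `GC`, `AU`, `GU`;
#'   given as negative energies, e.g. `c(GC = -3, AU = -2, GU = -1)`.
#' @return a [secondary_structure()]; `energy_score` is the sum of pair scores
#'   (<= 0).
#' @export
fold_nussinov <- function(sequence, min_loop = 3,
                          scoring = c(GC = -3, AU = -2, GU = -1)) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stopf("`sequence` must be a single non-empty string")
  }
  rna <- dna_to_rna(toupper(sequence))
  res <- .nussinov_cpp(rna, as.integer(min_loop),
                       as.integer(-scoring[["GC"]]),
                       as.integer(-scoring[["AU"]]),
                       as.integer(-scoring[["GU"]]))
  pairs <- cbind(i = res$pairs_i, j = res$pairs_j)
  if (nrow(pairs) > 0) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  secondary_structure(rna, res$dot_bracket, pairs, energy_score = -res$score)
}

#' Parse a dot-bracket string
#'
#' Vienna dialect: `(`, `)` and `.`. Errors on unbalanced brackets or a
#' length mismatch with the sequence.
#'
#' @param sequence nucleotide sequence.
#' @param dot_bracket structure string of equal length.
#' @return a [secondary_structure()] with the recovered pair list.
#' @export
parse_dotbracket <- function(sequence, dot_bracket) {
  if (nchar(sequence) != nchar(dot_bracket)) {
    stopf("sequence (%d nt) and structure (%d chars) lengths differ",
          nchar(sequence), nchar(dot_bracket))
  }
  ch <- strsplit(dot_bracket, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad) > 0) stopf("invalid structure characters: %s",
                             paste(bad, collapse = " "))
  open <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (length(open) == 0L) stopf("unbalanced brackets: ')' at position %d", k)
      i <- open[length(open)]
      open <- open[-length(open)]
      pi <- c(pi, i); pj <- c(pj, k)
    }
  }
  if (length(open) > 0L) stopf("unbalanced brackets: %d unclosed '('", length(open))
  pairs <- cbind(i = pi, j = pj)
  if (nrow(pairs) > 0) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  secondary_structure(sequence, dot_bracket, pairs)
}

#' Decompose a structure into helices
#'
#' A helix is a maximal run of nested, nearly-stacked base pairs; consecutive
#' pairs may be offset by interior gaps of at most `bulge_tol` unpaired bases
#' on either arm. Helices are reported with both arm intervals (1-based,
#' inclusive, spanning any interior bulges) and sorted by 5' position.
#'
#' @param structure a [secondary_structure()].
#' @param bulge_tol maximum per-arm gap (nt) between consecutive pairs of one
#'   helix.
#' @return data.frame: `five_start`, `five_end`, `three_start`, `three_end`,
#'   `n_pairs`.
#' @export
extract_helices <- function(structure, bulge_tol = 2) {
  p <- structure$pairs
  if (is.null(p) || nrow(p) == 0) {
    return(data.frame(five_start = integer(0), five_end = integer(0),
                      three_start = integer(0), three_end = integer(0),
                      n_pairs = integer(0)))
  }
  p <- p[order(p[, 1]), , drop = FALSE]
  groups <- list()
  cur <- 1L
  start <- 1L
  for (k in seq_len(nrow(p))[-1]) {
    gap5 <- p[k, 1] - p[k - 1, 1] - 1L
    gap3 <- p[k - 1, 2] - p[k, 2] - 1L
    nested <- p[k, 1] > p[k - 1, 1] && p[k, 2] < p[k - 1, 2]
    if (nested && gap5 <= bulge_tol && gap3 >= 0 && gap3 <= bulge_tol) {
      next
    }
    groups[[length(groups) + 1L]] <- start:(k - 1L)
    start <- k
  }
  groups[[length(groups) + 1L]] <- start:nrow(p)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(five_start = min(p[g, 1]), five_end = max(p[g, 1]),
               three_start = min(p[g, 2]), three_end = max(p[g, 2]),
               n_pairs = length(g))
  }))
  out[order(out$five_start), , drop = FALSE]
}

#' Classify a read interval against the helices of a structure
#'
#' The call behind a candidate report's "original read overlaps helix?"
#' column: with H the union of all helix arm intervals, a read is `TOTAL` if
#' every position lies in H, `NONE` if no position does, `PARTIAL` otherwise.
#' Arm intervals span small interior bulges (see [extract_helices()]), so a
#' read crossing a 1-2 nt bulge still classifies `TOTAL`.
#'
#' @param structure a [secondary_structure()].
#' @param read_start,read_end read interval, 1-based inclusive, within the
#'   structure span.
#' @param bulge_tol forwarded to [extract_helices()].
#' @return one of `"TOTAL"`, `"PARTIAL"`, `"NONE"`.
#' @export
classify_read_overlap <- function(structure, read_start, read_end,
                                  bulge_tol = 2) {
  n <- nchar(structure$sequence)
  if (read_start < 1 || read_end > n || read_start > read_end) {
    stopf("read interval [%d, %d] out of structure bounds [1, %d]",
          read_start, read_end, n)
  }
  h <- extract_helices(structure, bulge_tol = bulge_tol)
  inH <- rep(FALSE, n)
  for (k in seq_len(nrow(h))) {
    inH[h$five_start[k]:h$five_end[k]] <- TRUE
    inH[h$three_start[k]:h$three_end[k]] <- TRUE
  }
  cov <- inH[read_start:read_end]
  if (all(cov)) "TOTAL" else if (!any(cov)) "NONE" else "PARTIAL"
}

#' Hairpin features of a folded precursor
#'
#' Inputs to the built-in ab-initio score: global pairedness, the longest
#' helix, its loop and arm symmetry, stability per nucleotide, and how much of
#' the read is base-paired.
#'
#' @param structure a [secondary_structure()].
#' @param read_start,read_end the original read's interval inside the
#'   structure (1-based inclusive); `NULL` read yields `read_paired_fraction`
#'   of `NA`.
#' @param bulge_tol forwarded to [extract_helices()].
#' @return named list: `paired_fraction`, `longest_helix_pairs`,
#'   `loop_length`, `energy_per_nt`, `read_paired_fraction`, `arm_symmetry`.
#' @export
hairpin_features <- function(structure, read_start = NULL, read_end = NULL,
                             bulge_tol = 2) {
  n <- nchar(structure$sequence)
  np <- nrow(structure$pairs)
  paired <- rep(FALSE, n)
  if (np > 0) paired[c(structure$pairs[, 1], structure$pairs[, 2])] <- TRUE
  h <- extract_helices(structure, bulge_tol = bulge_tol)
  if (nrow(h) > 0) {
    top <- h[which.max(h$n_pairs), ]
    loop_len <- top$three_start - top$five_end - 1
    arm5 <- top$five_end - top$five_start + 1
    arm3 <- top$three_end - top$three_start + 1
    sym <- min(arm5, arm3) / max(arm5, arm3)
    longest <- top$n_pairs
  } else {
    loop_len <- NA_real_; sym <- 0; longest <- 0L
  }
  rpf <- NA_real_
  if (!is.null(read_start) && !is.null(read_end)) {
    rpf <- mean(paired[read_start:read_end])
  }
  list(paired_fraction = 2 * np / n,
       longest_helix_pairs = longest,
       loop_length = loop_len,
       energy_per_nt = structure$energy_score / n,
       read_paired_fraction = rpf,
       arm_symmetry = sym)
}

#' Inclusive lower quantile of precursor lengths
#'
#' The smallest length L such that at least a fraction `q` of the lengths are
#' <= L; the rule behind "98% of known precursors are shorter than 135 nt"
#' style summaries used to justify the +/-100 nt extension.
#'
#' @param lengths non-empty numeric vector.
#' @param q quantile in (0, 1].
#' @return a length value from `lengths`.
#' @export
length_quantile <- function(lengths, q = 0.98) {
  if (length(lengths) == 0) stopf("`lengths` must be non-empty")
  if (!is.numeric(q) || q <= 0 || q > 1) stopf("`q` must be in (0, 1]")
  s <- sort(lengths)
  s[which(seq_along(s) / length(s) >= q)[1]]
}
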