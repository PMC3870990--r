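# Mature miRNA quantification: contaminant filtering, end-anchored matching
# against a mature reference under a mismatch budget, the 5-hit /
# single-family collapse rule, and per-library counting with a conservation
# ledger. Identical reads are collapsed before matching and their copy counts
# carried, never recomputed.

#' Build a mature reference table
#'
#' One row per precursor locus. The family key defaults to stripping a
#' trailing `-<digit>` copy suffix from the precursor name (so
#' `hsa-mir-103a-1` and `hsa-mir-103a-2` share family `hsa-mir-103a`); an
#' explicit family map overrides.
#'
#' @param fasta data.frame from [read_fasta()] of mature sequences (header
#'   token = mature name).
#' @param family_map optional data.frame (`mature_name`, `precursor_id`,
#'   `family_key`); when absent every mature gets one precursor of the same
#'   name.
#' @return data.frame: `mature_name`, `precursor_id`, `family_key`,
#'   `sequence`.
#' @export
build_mature_reference <- function(fasta, family_map = NULL) {
  if (is.null(family_map)) {
    return(data.frame(mature_name = fasta$name, precursor_id = fasta$name,
                      family_key = family_key_from_name(fasta$name),
                      sequence = rna_to_dna(fasta$sequence),
                      stringsAsFactors = FALSE))
  }
  m <- match(family_map$mature_name, fasta$name)
  if (anyNA(m)) {
    stopf("family map names missing from mature FASTA: %s",
          paste(family_map$mature_name[is.na(m)], collapse = ", "))
  }
  data.frame(mature_name = family_map$mature_name,
             precursor_id = family_map$precursor_id,
             family_key = family_map$family_key,
             sequence = rna_to_dna(fasta$sequence[m]),
             stringsAsFactors = FALSE)
}

#' Filter contaminant reads
#'
#' Removes reads matching any rRNA/tRNA/repeat/adapter record, either as an
#' exact substring of the contaminant or as a full-length match within the
#' mismatch budget, and tallies removals per class.
#'
#' @param reads read records (`id`, `sequence`, `count`, `library_id`).
#' @param contaminant_db data.frame with `name`, `class`, `sequence` (class
#'   labels are required).
#' @param max_mismatch substitution budget for the substring match.
#' @return list: `kept` (read records), `removed` (read records plus
#'   `class`), `tally` (per-class removed copy counts). Kept plus removed
#'   equals the input, by copies.
#' @export
filter_contaminants <- function(reads, contaminant_db, max_mismatch = 0) {
  if (nrow(contaminant_db) > 0 &&
      (is.null(contaminant_db$class) || anyNA(contaminant_db$class) ||
       any(!nzchar(contaminant_db$class)))) {
    stopf("every contaminant record needs a class label")
  }
  hit_class <- rep(NA_character_, nrow(reads))
  if (nrow(contaminant_db) > 0 && nrow(reads) > 0) {
    subjects <- Biostrings::DNAStringSet(contaminant_db$sequence)
    for (k in seq_len(nrow(reads))) {
      n <- Biostrings::vcountPattern(reads$sequence[k], subjects,
                                     max.mismatch = max_mismatch)
      h <- which(n > 0)
      if (length(h) > 0) hit_class[k] <- contaminant_db$class[h[1]]
    }
  }
  removed <- reads[!is.na(hit_class), , drop = FALSE]
  removed$class <- hit_class[!is.na(hit_class)]
  kept <- reads[is.na(hit_class), , drop = FALSE]
  tally <- if (nrow(removed) > 0) {
    stats::aggregate(count ~ class, data = removed, FUN = sum)
  } else data.frame(class = character(0), count = integer(0))
  list(kept = kept, removed = removed, tally = tally)
}

#' Match a read against the mature reference
#'
#' End-anchored matching: the mature sequence is slid across the read with a
#' terminal offset of at most `max_shift` nt (mature overhang beyond the read
#' also counts against the shift budget) and at most `max_mismatch`
#' substitutions over the overlap; `N` counts as a mismatch. One hit per
#' reference row (precursor locus), with its mismatch count.
#'
#' @param read a single read sequence (>= 15 nt).
#' @param reference mature reference table (see [build_mature_reference()]).
#' @param max_mismatch substitution budget (default 2).
#' @param max_shift terminal offset budget (default 2).
#' @return data.frame of hits: `mature_name`, `precursor_id`, `family_key`,
#'   `mismatches`.
#' @export
match_mature <- function(read, reference, max_mismatch = 2, max_shift = 2) {
  read <- toupper(read)
  if (nchar(read) < 15) stopf("read must be >= 15 nt")
  mm <- vapply(reference$sequence, function(ref)
    .anchored_mismatch_cpp(read, ref, as.integer(max_mismatch),
                           as.integer(max_shift)),
    integer(1), USE.NAMES = FALSE)
  hits <- reference[mm >= 0, c("mature_name", "precursor_id", "family_key"),
                    drop = FALSE]
  hits$mismatches <- mm[mm >= 0]
  rownames(hits) <- NULL
  hits
}

#' Assign a read from its hit list
#'
#' The multi-hit collapse rule: no hit is `unmatched`; a unique hit is
#' assigned to the mature name; 2 to `max_hits` hits all within one miRNA
#' family are collapsed and assigned to the family key (reads hitting
#' `hsa-mir-103a-1` and `hsa-mir-103a-2` count as `hsa-mir-103a`); more than
#' `max_hits` hits, or hits spanning two or more families, are discarded.
#'
#' @param hits hit table from [match_mature()].
#' @param max_hits maximum tolerated number of hits (default 5).
#' @param cap_on `"precursors"` (default) caps the number of distinct
#'   precursor hits; `"families"` caps after collapsing family variants.
#' @return list: `status` (one of `assigned`, `discarded_multihit`,
#'   `unmatched`), `label` (mature or family key; NA unless assigned),
#'   `n_hits`.
#' @export
assign_read <- function(hits, max_hits = 5,
                        cap_on = c("precursors", "families")) {
  cap_on <- match.arg(cap_on)
  n <- length(unique(hits$precursor_id))
  if (n == 0) return(list(status = "unmatched", label = NA_character_, n_hits = 0L))
  fams <- unique(hits$family_key)
  n_capped <- if (cap_on == "precursors") n else length(fams)
  if (n_capped > max_hits || length(fams) > 1) {
    return(list(status = "discarded_multihit", label = NA_character_,
                n_hits = n))
  }
  label <- if (n == 1) hits$mature_name[1] else fams[1]
  list(status = "assigned", label = label, n_hits = n)
}

#' Quantify assigned reads into an expression profile
#'
#' Runs [filter_contaminants()], [match_mature()] and [assign_read()] over
#' one library's collapsed reads and sums copy counts per label. The ledger
#' accounts for every input copy: contaminant, unmatched, discarded and
#' assigned tallies sum to the input total.
#'
#' @param reads read records for one library.
#' @param reference mature reference table.
#' @param contaminant_db contaminant table (`name`, `class`, `sequence`); NULL
#'   to skip filtering.
#' @param library_id library label (defaults to the reads' common library).
#' @param max_mismatch,max_shift,max_hits,cap_on matching/assignment
#'   parameters, see [match_mature()] and [assign_read()].
#' @return an `expression_profile`: list with `library_id`, `entries`
#'   (data.frame `label`, `raw_count`, `n_reads`), `ledger` (named copy
#'   totals), `assignments` (per unique read), `unmatched` (read records for
#'   the discovery branch).
#' @export
quantify <- function(reads, reference, contaminant_db = NULL,
                     library_id = NULL, max_mismatch = 2, max_shift = 2,
                     max_hits = 5, cap_on = "precursors") {
  library_id <- library_id %||% unique(reads$library_id)
  if (length(library_id) != 1) stopf("reads must come from a single library")
  if (nrow(reads) > 0 && any(reads$library_id != library_id)) {
    stopf("all reads must belong to library %s", library_id)
  }
  total_in <- sum(reads$count)
  if (!is.null(contaminant_db)) {
    fc <- filter_contaminants(reads, contaminant_db)
  } else {
    fc <- list(kept = reads,
               removed = cbind(reads[0, , drop = FALSE],
                               class = character(0)),
               tally = data.frame(class = character(0), count = integer(0)))
  }
  kept <- fc$kept
  status <- character(nrow(kept))
  label <- character(nrow(kept))
  n_hits <- integer(nrow(kept))
  for (k in seq_len(nrow(kept))) {
    a <- assign_read(match_mature(kept$sequence[k], reference,
                                  max_mismatch = max_mismatch,
                                  max_shift = max_shift),
                     max_hits = max_hits, cap_on = cap_on)
    status[k] <- a$status; label[k] <- a$label; n_hits[k] <- a$n_hits
  }
  assignments <- cbind(kept, status = status, label = label, n_hits = n_hits)
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  entries <- if (nrow(asg) > 0) {
    e <- stats::aggregate(cbind(raw_count = count) ~ label, data = asg, FUN = sum)
    e$n_reads <- stats::aggregate(count ~ label, data = asg, FUN = length)$count
    e[order(e$label), , drop = FALSE]
  } else data.frame(label = character(0), raw_count = integer(0),
                    n_reads = integer(0))
  rownames(entries) <- NULL
  ledger <- c(
    total = total_in,
    contaminant = sum(fc$removed$count),
    unmatched = sum(assignments$count[assignments$status == "unmatched"]),
    discarded_multihit = sum(assignments$count[assignments$status ==
                                                 "discarded_multihit"]),
    assigned = sum(asg$count)
  )
  structure(list(library_id = library_id, entries = entries, ledger = ledger,
                 contaminant_tally = fc$tally, assignments = assignments,
                 unmatched = assignments[assignments$status == "unmatched",
                                         c("id", "sequence", "count",
                                           "library_id"), drop = FALSE]),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile '%s': %d labels, %d assigned copies\n",
              x$library_id, nrow(x$entries), x$ledger[["assigned"]]))
  cat(sprintf("  ledger: total %d = contaminant %d + unmatched %d + discarded %d + assigned %d\n",
              x$ledger[["total"]], x$ledger[["contaminant"]],
              x$ledger[["unmatched"]], x$ledger[["discarded_multihit"]],
              x$ledger[["assigned"]]))
  invisible(x)
}
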