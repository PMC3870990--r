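# Evidence integration: seeded similarity search against a curated ncRNA
# database, false-positive exclusion, adapters for external structural
# (INFERNAL-style) and ab-initio score files, a built-in logistic ab-initio
# stand-in, mature/star proposals, and the tiered verdict that
# operationalizes manual curation.

#' Seeded similarity search of a candidate against an ncRNA database
#'
#' Candidate/subject pairs sharing at least one `word_size`-mer seed - exact
#' or within one substitution (a neighborhood word, the usual seeding
#' sensitivity device) - are aligned locally (Smith-Waterman, match +1,
#' mismatch -1, gap -2); a hit is
#' retained iff identity >= `min_identity` and query or subject coverage >=
#' `min_coverage`. A Karlin-Altschul-style `evalue_proxy` (lambda = ln 3 for
#' the +1/-1 scoring, K = 1/3) acts as the significance pre-filter: hits
#' above `max_evalue` are dropped before the identity/coverage rule decides
#' retention. Set `max_evalue = Inf` to study the bare 80/80 rule.
#'
#' @param candidate a `candidate_locus` (or a list with `candidate_id` and
#'   `precursor_sequence`).
#' @param ncrna_db data.frame with `name`, `type`, `sequence`; type labels
#'   are required.
#' @param word_size seed word length (default 6).
#' @param min_identity percent identity cutoff (default 80).
#' @param min_coverage percent coverage cutoff on either side (default 80).
#' @param max_evalue e-value-proxy pre-filter (default 1e-4); `Inf` disables.
#' @return data.frame of retained hits: `candidate_id`, `subject_id`,
#'   `subject_type`, `score`, `identity`, `query_coverage`,
#'   `subject_coverage`, `evalue_proxy`, `evalue_ok`.
#' @export
similarity_search <- function(candidate, ncrna_db, word_size = 6,
                              min_identity = 80, min_coverage = 80,
                              max_evalue = 1e-4) {
  if (is.null(ncrna_db) || nrow(ncrna_db) == 0) stopf("ncRNA database is empty")
  if (is.null(ncrna_db$type) || any(!nzchar(ncrna_db$type))) {
    stopf("every ncRNA database record needs a type label")
  }
  query <- rna_to_dna(toupper(candidate$precursor_sequence))
  qlen <- nchar(query)
  db_len <- sum(nchar(ncrna_db$sequence))
  qwords <- unique(substring(query, seq_len(max(qlen - word_size + 1L, 0L)),
                             seq_len(max(qlen - word_size + 1L, 0L)) +
                               word_size - 1L))
  qmat <- do.call(rbind, strsplit(qwords, "", fixed = TRUE))
  lambda <- log(3); K <- 1 / 3
  out <- list()
  for (k in seq_len(nrow(ncrna_db))) {
    subject <- rna_to_dna(toupper(ncrna_db$sequence[k]))
    slen <- nchar(subject)
    if (slen < word_size) next
    swords <- unique(substring(subject, seq_len(slen - word_size + 1L),
                               seq_len(slen - word_size + 1L) + word_size - 1L))
    if (!any(swords %in% qwords)) {
      # neighborhood seeding: a shared word within one substitution
      smat <- do.call(rbind, strsplit(swords, "", fixed = TRUE))
      mm <- matrix(0L, nrow(qmat), nrow(smat))
      for (p in seq_len(word_size)) {
        mm <- mm + outer(qmat[, p], smat[, p], "!=")
      }
      if (!any(mm <= 1L)) next
    }
    al <- .smith_waterman_cpp(query, subject, 1L, -1L, -2L)
    if (al$score <= 0) next
    identity <- 100 * al$matches / al$align_len
    qcov <- 100 * (al$a_end - al$a_start + 1) / qlen
    scov <- 100 * (al$b_end - al$b_start + 1) / slen
    if (identity < min_identity) next
    if (qcov < min_coverage && scov < min_coverage) next
    ev <- K * qlen * db_len * exp(-lambda * al$score)
    if (is.finite(max_evalue) && ev > max_evalue) next
    out[[length(out) + 1L]] <- data.frame(
      candidate_id = candidate$candidate_id, subject_id = ncrna_db$name[k],
      subject_type = ncrna_db$type[k], score = al$score,
      identity = identity, query_coverage = qcov, subject_coverage = scov,
      evalue_proxy = ev, evalue_ok = ev <= max_evalue,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(candidate_id = character(0), subject_id = character(0),
               subject_type = character(0), score = integer(0),
               identity = numeric(0), query_coverage = numeric(0),
               subject_coverage = numeric(0), evalue_proxy = numeric(0),
               evalue_ok = logical(0))
}

#' Exclude false-positive candidates
#'
#' The conservative screen: a candidate is excluded when it (in priority
#' order) overlaps a known exon, matches a non-miRNA ncRNA type in the
#' database above the similarity cutoffs, or is called a tRNA (by an external
#' caller's output or by overlap with tRNA-typed annotation). miRNA and
#' "unclassified RNA" similarity hits never exclude.
#'
#' @param candidates list of `candidate_locus` objects (context assigned, see
#'   [assign_genomic_context()]).
#' @param annotation GRanges used for exon/tRNA overlap (NULL for none).
#' @param similarity_hits combined hit table from [similarity_search()].
#' @param trna_calls character vector of candidate ids postulated as tRNAs by
#'   an external caller.
#' @return list: `kept` (candidates), `excluded` (data.frame `candidate_id`,
#'   `reason` - one primary reason each). Kept plus excluded partition the
#'   input.
#' @export
exclude_false_positives <- function(candidates, annotation = NULL,
                                    similarity_hits = NULL,
                                    trna_calls = character(0)) {
  if (length(candidates) == 0) {
    return(list(kept = candidates,
                excluded = data.frame(candidate_id = character(0),
                                      reason = character(0))))
  }
  # candidates may arrive without context when no annotation was supplied
  no_ctx <- vapply(candidates, function(x) is.na(x$genomic_context), TRUE)
  if (any(no_ctx)) candidates <- assign_genomic_context(candidates, annotation)
  ids <- vapply(candidates, `[[`, "", "candidate_id")
  reason <- rep(NA_character_, length(candidates))

  trna_overlap <- rep(FALSE, length(candidates))
  if (!is.null(annotation) && length(annotation) > 0) {
    tr <- annotation[as.character(annotation$type) %in% c("tRNA", "tRNA_gene")]
    if (length(tr) > 0) {
      gr <- candidates_to_granges(candidates)
      trna_overlap <- GenomicRanges::countOverlaps(gr, tr) > 0
    }
  }
  bad_sim <- character(0)
  if (!is.null(similarity_hits) && nrow(similarity_hits) > 0) {
    ncol_bad <- !(similarity_hits$subject_type %in%
                    c("miRNA", "unclassified RNA"))
    bad_sim <- unique(similarity_hits$candidate_id[ncol_bad])
  }
  for (k in seq_along(candidates)) {
    if (identical(candidates[[k]]$genomic_context, "exon")) {
      reason[k] <- "exon_overlap"
    } else if (ids[k] %in% bad_sim) {
      reason[k] <- "non_miRNA_ncRNA_match"
    } else if (ids[k] %in% trna_calls || trna_overlap[k]) {
      reason[k] <- "tRNA_call"
    }
  }
  list(kept = candidates[is.na(reason)],
       excluded = data.frame(candidate_id = ids[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Parse INFERNAL-style tabular output into family hits
#'
#' Reads the cmsearch `--tblout` dialect: '#'-prefixed comments, then
#' whitespace-separated columns (target, target accession, query/family,
#' family accession, model, model from/to, sequence from/to, strand, trunc,
#' pass, gc, bias, bit score, e-value, inclusion, description). Rows scoring
#' below `cutoff` are dropped; coordinates are normalized so start <= end
#' (1-based inclusive, candidate-local) with the strand kept.
#'
#' @param path tblout file.
#' @param cutoff minimum bit score (default 25).
#' @return data.frame: `candidate_id`, `family_id`, `family_acc`,
#'   `bit_score`, `start`, `end`, `strand`.
#' @export
parse_infernal_tblout <- function(path, cutoff = 25) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 15) {
      stopf("malformed tblout row at line %d: expected >= 15 columns, got %d",
            ln, length(f))
    }
    score <- suppressWarnings(as.numeric(f[15]))
    from <- suppressWarnings(as.integer(f[8]))
    to <- suppressWarnings(as.integer(f[9]))
    if (is.na(score) || is.na(from) || is.na(to)) {
      stopf("malformed tblout row at line %d: non-numeric coordinates/score", ln)
    }
    if (score < cutoff) next
    out[[length(out) + 1L]] <- data.frame(
      candidate_id = f[1], family_id = f[3], family_acc = f[4],
      bit_score = score, start = min(from, to), end = max(from, to),
      strand = f[10], stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(candidate_id = character(0), family_id = character(0),
               family_acc = character(0), bit_score = numeric(0),
               start = integer(0), end = integer(0), strand = character(0))
}

#' Read an ab-initio classifier score file
#'
#' Two whitespace-separated columns: candidate id, score in the unit interval.
#' Sub-threshold scores are recorded and flagged rather than dropped: the
#' verdict tiers, not the raw cutoff, weigh them.
#'
#' @param path score file.
#' @param cutoff recommended decision threshold (default 0.71).
#' @return data.frame: `candidate_id`, `score`, `passes_cutoff`.
#' @export
read_hhmmir_scores <- function(path, cutoff = 0.71) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\\s+")[[1]]
    score <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2 || is.na(score)) {
      stopf("malformed score row at line %d: need '<id> <score>'", ln)
    }
    out[[length(out) + 1L]] <- data.frame(
      candidate_id = f[1], score = score, passes_cutoff = score >= cutoff,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(candidate_id = character(0), score = numeric(0),
               passes_cutoff = logical(0))
}

#' Frozen weights of the built-in ab-initio score
#'
#' Logistic-regression coefficients over hairpin features, calibrated once on
#' the package's reference synthetic fixture (planted hairpin precursors as
#' positives, dinucleotide-shuffled precursors as negatives) and frozen here.
#'
#' @return named numeric vector of coefficients.
#' @export
abinitio_weights <- function() {
  c(intercept = -68.1277,
    paired_fraction = 7.0784,
    energy_per_nt = -32.4300,
    loop_length = -0.0043,
    read_paired_fraction = 27.8880,
    longest_helix_pairs = 0.3381)
}

#' Built-in ab-initio hairpin score
#'
#' A logistic combination of [hairpin_features()] - global pairedness,
#' stability per nucleotide, loop length, the read's paired fraction and the
#' longest helix - standing in for an external hairpin classifier. Scores lie
#' in the unit interval; the companion decision threshold is 0.71.
#'
#' @param features list from [hairpin_features()].
#' @param weights coefficient vector (default [abinitio_weights()]).
#' @return numeric score in the unit interval.
#' @export
score_abinitio <- function(features, weights = abinitio_weights()) {
  x <- c(1,
         features$paired_fraction,
         features$energy_per_nt,
         if (is.na(features$loop_length)) 0 else features$loop_length,
         if (is.na(features$read_paired_fraction)) 0 else
           features$read_paired_fraction,
         features$longest_helix_pairs)
  as.numeric(stats::plogis(sum(x * weights)))
}

#' Propose mature and star sequences within a candidate precursor
#'
#' Proposal 1 is the original (most abundant) read itself, provided it
#' overlaps a helix at least partially; proposal 2 is the star: the positions
#' paired to the read, shifted by the characteristic 2 nt 3' overhang
#' (star_begin = partner(read_end) + 2, star_end = partner(read_begin) + 2).
#' A read lying entirely in loops yields no proposals.
#'
#' @param candidate a `candidate_locus`.
#' @param structure the folded precursor ([secondary_structure()]).
#' @return data.frame of proposals: `proposal` (`read`/`star`), `start`,
#'   `end` (1-based precursor coordinates), `sequence`, `arm` (`5p`/`3p`).
#' @export
propose_mature <- function(candidate, structure) {
  empty <- data.frame(proposal = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      arm = character(0))
  h <- extract_helices(structure)
  if (nrow(h) == 0 || nrow(candidate$reads) == 0) return(empty)
  rd <- candidate$reads[which.max(candidate$reads$count), ]
  ov <- classify_read_overlap(structure, rd$prec_start, rd$prec_end)
  if (ov == "NONE") return(empty)
  p <- structure$pairs
  partner <- integer(nchar(structure$sequence))
  partner[p[, 1]] <- p[, 2]; partner[p[, 2]] <- p[, 1]
  rp <- rd$prec_start:rd$prec_end
  partners <- partner[rp]
  partners <- partners[partners > 0]
  if (length(partners) == 0) return(empty)
  n <- nchar(structure$sequence)
  star_start <- max(1L, min(partners) + 2L)
  star_end <- min(n, max(partners) + 2L)
  read_arm <- if (mean(partners) > mean(rp)) "5p" else "3p"
  star_arm <- if (read_arm == "5p") "3p" else "5p"
  data.frame(
    proposal = c("read", "star"),
    start = c(rd$prec_start, star_start),
    end = c(rd$prec_end, star_end),
    sequence = c(substr(rna_to_dna(structure$sequence), rd$prec_start,
                        rd$prec_end),
                 substr(rna_to_dna(structure$sequence), star_start, star_end)),
    arm = c(read_arm, star_arm),
    stringsAsFactors = FALSE)
}

# Does any pair of this candidate's reads cover the two arms of one stem?
two_arm_support <- function(candidate, structure, min_duplex_pairs = 5) {
  if (length(candidate$merged_from) > 0) return(TRUE)
  rd <- candidate$reads
  if (nrow(rd) < 2) return(FALSE)
  for (i in seq_len(nrow(rd) - 1)) {
    for (j in (i + 1):nrow(rd)) {
      if (reads_duplex_pairs(structure, rd$prec_start[i], rd$prec_end[i],
                             rd$prec_start[j], rd$prec_end[j]) >=
          min_duplex_pairs) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Integrate all evidence for one candidate into a verdict record
#'
#' The tier rules (deterministic, monotone in the evidence):
#' * `excluded` - failed a false-positive rule (reason recorded), regardless
#'   of other evidence;
#' * `strong` - the candidate's reads cover both arms of one stem (a merged
#'   or two-arm candidate), or a structural family hit covers at least half
#'   of the read while the read overlaps a helix;
#' * `supported` - at least one positive channel (similarity, family,
#'   ab-initio >= cutoff) with the read in a stem, or two or more positive
#'   channels;
#' * `weak` - anything else (including sub-threshold ab-initio scores, which
#'   are recorded but not counted as a positive channel).
#'
#' @param candidate a `candidate_locus`.
#' @param structure the folded precursor.
#' @param similarity_hits retained hits for this candidate (or NULL).
#' @param family_hits family hits for this candidate (or NULL; already
#'   cutoff-filtered by [parse_infernal_tblout()]).
#' @param abinitio_score numeric score or NA.
#' @param excluded_reason NA or the exclusion reason.
#' @param norm_counts named per-library normalized counts for the candidate's
#'   reads.
#' @param abinitio_cutoff decision threshold (default 0.71).
#' @param min_family_read_cov fraction of the read a family hit must cover to
#'   anchor a strong verdict (default 0.5).
#' @return an `evidence_record` list with all channels, the read-overlap
#'   class and `verdict_tier`.
#' @export
integrate_evidence <- function(candidate, structure, similarity_hits = NULL,
                               family_hits = NULL, abinitio_score = NA,
                               excluded_reason = NA_character_,
                               norm_counts = numeric(0),
                               abinitio_cutoff = 0.71,
                               min_family_read_cov = 0.5) {
  rd <- candidate$reads[which.max(candidate$reads$count), ]
  overlap <- classify_read_overlap(structure, rd$prec_start, rd$prec_end)
  sim_pos <- !is.null(similarity_hits) && nrow(similarity_hits) > 0
  fam_pos <- !is.null(family_hits) && nrow(family_hits) > 0
  ab_pos <- !is.na(abinitio_score) && abinitio_score >= abinitio_cutoff
  n_channels <- sum(sim_pos, fam_pos, ab_pos)

  fam_covers <- FALSE
  if (fam_pos) {
    ov_len <- pmin(family_hits$end, rd$prec_end) -
      pmax(family_hits$start, rd$prec_start) + 1
    fam_covers <- any(ov_len / (rd$prec_end - rd$prec_start + 1) >=
                        min_family_read_cov)
  }
  two_arm <- two_arm_support(candidate, structure)

  tier <- if (!is.na(excluded_reason)) {
    "excluded"
  } else if (two_arm || (fam_covers && overlap != "NONE")) {
    "strong"
  } else if ((n_channels >= 1 && overlap != "NONE") || n_channels >= 2) {
    "supported"
  } else {
    "weak"
  }
  structure(list(candidate_id = candidate$candidate_id,
                 genomic_context = candidate$genomic_context,
                 norm_counts = norm_counts,
                 similarity_hits = similarity_hits,
                 family_hits = family_hits,
                 abinitio_score = abinitio_score,
                 energy = structure$energy_score,
                 read_overlap = overlap,
                 two_arm = two_arm,
                 excluded_reason = excluded_reason,
                 verdict_tier = tier),
            class = "evidence_record")
}

#' @export
print.evidence_record <- function(x, ...) {
  cat(sprintf("evidence_record %s: tier %s (overlap %s, ab-initio %s, context %s)\n",
              x$candidate_id, x$verdict_tier, x$read_overlap,
              ifelse(is.na(x$abinitio_score), "-",
                     sprintf("%.2f", x$abinitio_score)),
              x$genomic_context %||% "NA"))
  invisible(x)
}

#' Tabulate evidence records into a candidate report
#'
#' One row per candidate: genomic location class, per-library normalized
#' counts, a similarity summary (best hit with coverages and identity),
#' ab-initio score, read-overlap class, energy, family hits and verdict tier.
#'
#' @param records list of `evidence_record` objects.
#' @return data.frame.
#' @export
evidence_table <- function(records) {
  libs <- sort(unique(unlist(lapply(records, function(r) names(r$norm_counts)))))
  rows <- lapply(records, function(r) {
    sim <- "-"
    if (!is.null(r$similarity_hits) && nrow(r$similarity_hits) > 0) {
      b <- r$similarity_hits[which.max(r$similarity_hits$score), ]
      sim <- sprintf("%s type=%s qcov=%.0f%% scov=%.0f%% id=%.0f%%",
                     b$subject_id, b$subject_type, b$query_coverage,
                     b$subject_coverage, b$identity)
    }
    fam <- "-"
    if (!is.null(r$family_hits) && nrow(r$family_hits) > 0) {
      fam <- paste(sprintf("%s(%s) bits=%.2f %d-%d", r$family_hits$family_id,
                           r$family_hits$strand, r$family_hits$bit_score,
                           r$family_hits$start, r$family_hits$end),
                   collapse = "; ")
    }
    base <- data.frame(candidate_id = r$candidate_id,
                       genomic_location = r$genomic_context %||% NA_character_,
                       stringsAsFactors = FALSE)
    for (lib in libs) {
      base[[paste0("norm_", lib)]] <-
        if (lib %in% names(r$norm_counts)) r$norm_counts[[lib]] else 0
    }
    base$similarity <- sim
    base$abinitio_score <- r$abinitio_score
    base$read_overlaps_helix <- r$read_overlap
    base$energy <- r$energy
    base$family_hits <- fam
    base$excluded_reason <- r$excluded_reason
    base$verdict_tier <- r$verdict_tier
    base
  })
  do.call(rbind, rows)
}
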