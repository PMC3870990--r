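# Expression analysis: max-normalization, the pure 2-fold differential
# expression rule, uniquely expressed molecules, top-N representation and
# common-miRNA percentages between sample pairs.

#' Normalize an expression profile by its maximum
#'
#' Each raw count is divided by the library's highest raw count (times
#' `scale`), so the most abundant molecule gets value `scale` and all others
#' are relative abundances. An all-zero profile normalizes to all zeros. A
#' `"global"` mode divides every library by one shared maximum instead (pass
#' it via `global_max`).
#'
#' @param profile an `expression_profile` from [quantify()], or a data.frame
#'   with `label` and `raw_count`.
#' @param scale value assigned to the library maximum (default 1.0).
#' @param global_max optional externally supplied maximum (global mode).
#' @return the profile with a `normalized` column added to its entries.
#' @export
normalize_max <- function(profile, scale = 1.0, global_max = NULL) {
  entries <- if (inherits(profile, "expression_profile")) profile$entries
             else profile
  if (is.null(entries) || nrow(entries) == 0) stopf("profile has no entries")
  mx <- global_max %||% max(entries$raw_count)
  entries$normalized <- if (mx > 0) entries$raw_count / mx * scale else 0
  if (inherits(profile, "expression_profile")) {
    profile$entries <- entries
    profile$scale <- scale
    profile
  } else entries
}

entries_of <- function(x) {
  if (inherits(x, "expression_profile")) x$entries else x
}

#' Call differential expression between two normalized profiles
#'
#' The fold-change rule: a label enters the table iff both normalized values
#' reach the expression floor and the larger-over-smaller ratio is at least
#' `min_fold`. Zero-vs-nonzero labels never enter (they are the province of
#' [unique_expressed()]); the default floor is the smallest nonzero
#' normalized value seen in either profile, i.e. "observed at all".
#'
#' @param prof_a,prof_b normalized profiles (see [normalize_max()]).
#' @param min_fold minimum fold change (default 2).
#' @param floor minimum normalized expression on both sides; labels with a
#'   value below it are not testable.
#' @return data.frame: `label`, `norm_a`, `norm_b`, `fold_change` (>= 1),
#'   `direction` (`"A"`/`"B"`, the higher side; `"none"` at fold 1 is never
#'   reported since fold 1 < `min_fold` for any sensible threshold).
#' @export
call_differential <- function(prof_a, prof_b, min_fold = 2.0, floor = NULL) {
  ea <- entries_of(prof_a); eb <- entries_of(prof_b)
  if (is.null(ea$normalized) || is.null(eb$normalized)) {
    stopf("profiles must be normalized first (see normalize_max)")
  }
  labels <- sort(union(ea$label, eb$label))
  na <- ea$normalized[match(labels, ea$label)]
  nb <- eb$normalized[match(labels, eb$label)]
  na[is.na(na)] <- 0; nb[is.na(nb)] <- 0
  if (is.null(floor)) {
    pos <- c(na[na > 0], nb[nb > 0])
    floor <- if (length(pos)) min(pos) else 0
  }
  ok <- na >= floor & nb >= floor & na > 0 & nb > 0
  fold <- pmax(na, nb) / pmin(na, nb)
  keep <- ok & fold >= min_fold
  out <- data.frame(label = labels[keep],
                    norm_a = na[keep], norm_b = nb[keep],
                    fold_change = fold[keep],
                    direction = ifelse(na[keep] >= nb[keep], "A", "B"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$fold_change, out$label), , drop = FALSE]
}

#' Uniquely expressed labels between two profiles
#'
#' A label is unique to one sample iff its raw count there reaches
#' `min_count` and the other sample has zero copies.
#'
#' @param prof_a,prof_b profiles (raw counts used).
#' @param min_count detection cutoff (default 10 reads).
#' @return list: `unique_a`, `unique_b` (character vectors of labels).
#' @export
unique_expressed <- function(prof_a, prof_b, min_count = 10) {
  ea <- entries_of(prof_a); eb <- entries_of(prof_b)
  labels <- sort(union(ea$label, eb$label))
  ra <- ea$raw_count[match(labels, ea$label)]
  rb <- eb$raw_count[match(labels, eb$label)]
  ra[is.na(ra)] <- 0; rb[is.na(rb)] <- 0
  list(unique_a = labels[ra >= min_count & rb == 0],
       unique_b = labels[rb >= min_count & ra == 0])
}

#' Top expressed labels and their cumulative share
#'
#' @param profile a profile (raw counts used).
#' @param n how many top labels (>= 1).
#' @return data.frame of the top `n` labels sorted by raw count descending
#'   (ties broken lexicographically), with `cumulative_fraction` of all
#'   assigned copies.
#' @export
top_expressed <- function(profile, n = 10) {
  if (n < 1) stopf("`n` must be >= 1")
  e <- entries_of(profile)
  if (nrow(e) == 0) stopf("profile has no entries")
  e <- e[order(-e$raw_count, e$label), , drop = FALSE]
  n <- min(n, nrow(e))
  out <- e[seq_len(n), c("label", "raw_count"), drop = FALSE]
  out$cumulative_fraction <- cumsum(out$raw_count) / sum(e$raw_count)
  rownames(out) <- NULL
  out
}

#' Percentage of a sample's miRNAs shared with a reference set
#'
#' `100 * |sample intersect reference| / |sample|`, rounded half-up to two
#' decimals - the "% of common miRNAs with related cell type" summary.
#'
#' @param detected_sample,detected_reference character vectors of detected
#'   labels (raw count >= 1).
#' @return numeric percentage.
#' @export
common_mirna_percentage <- function(detected_sample, detected_reference) {
  detected_sample <- unique(detected_sample)
  if (length(detected_sample) == 0) stopf("sample set is empty")
  shared <- length(intersect(detected_sample, unique(detected_reference)))
  round_half_up(100 * shared / length(detected_sample), 2)
}
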