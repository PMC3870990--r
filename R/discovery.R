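# Novel-miRNA candidate discovery: selection of abundant short unmatched
# reads, exact genome mapping on both strands, positional clustering,
# +/-100 nt extension into putative precursors, genomic-context assignment
# and merging of adjacent candidates whose reads cover the two arms of one
# stem.

#' Select reads for the discovery branch
#'
#' Keeps unmatched reads shorter than `max_len` nt with at least `min_copies`
#' copies. The copy threshold is inclusive (>= 10) by default; set
#' `strict_copies` for the strict reading (> 10).
#'
#' @param unmatched_reads read records (`id`, `sequence`, `count`,
#'   `library_id`).
#' @param min_copies copy-number floor (default 10).
#' @param max_len reads must be shorter than this (default 35 nt, exclusive).
#' @param strict_copies require strictly more than `min_copies` copies.
#' @return the selected read records.
#' @export
select_discovery_reads <- function(unmatched_reads, min_copies = 10,
                                   max_len = 35, strict_copies = FALSE) {
  len_ok <- nchar(unmatched_reads$sequence) < max_len
  cp <- unmatched_reads$count
  cp_ok <- if (strict_copies) cp > min_copies else cp >= min_copies
  out <- unmatched_reads[len_ok & cp_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map reads to the genome by exact match
#'
#' Exact full-length placements on both strands (via
#' [Biostrings::matchPattern()]); reads with more than `max_loci` placements
#' are dropped and logged. For a minus-strand placement the reverse
#' complement of the genomic interval equals the read.
#'
#' @param reads read records.
#' @param genome named character vector of chromosome sequences.
#' @param max_loci maximum tolerated placements per read (default 5).
#' @return list: `mapped` (data.frame `id`, `sequence`, `count`,
#'   `library_id`, `chrom`, `start`, `end`, `strand`; 1-based inclusive),
#'   `dropped` (read ids with placement counts beyond the cap or zero).
#' @export
map_reads_exact <- function(reads, genome, max_loci = 5) {
  gset <- Biostrings::DNAStringSet(unname(genome))
  names(gset) <- names(genome)
  rows <- list()
  dropped <- list()
  for (k in seq_len(nrow(reads))) {
    seqs <- c(`+` = reads$sequence[k], `-` = revcomp(reads$sequence[k]))
    placements <- list()
    for (chrom in names(gset)) {
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPattern(seqs[[strand]], gset[[chrom]])
        if (length(m) > 0) {
          placements[[length(placements) + 1L]] <- data.frame(
            chrom = chrom, start = BiocGenerics::start(m),
            end = BiocGenerics::end(m), strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
    pl <- if (length(placements)) do.call(rbind, placements) else NULL
    n_pl <- if (is.null(pl)) 0L else nrow(pl)
    if (n_pl == 0L || n_pl > max_loci) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        id = reads$id[k], n_placements = n_pl,
        reason = if (n_pl == 0L) "no_placement" else "multimapped",
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      reads[rep(k, n_pl), c("id", "sequence", "count", "library_id"),
            drop = FALSE],
      pl, row.names = NULL)
  }
  mapped <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), sequence = character(0), count = integer(0),
               library_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(id = character(0), n_placements = integer(0),
               reason = character(0))
  list(mapped = mapped, dropped = dropped)
}

#' Cluster mapped reads by genomic position
#'
#' Reads on the same chromosome and strand whose intervals overlap or are
#' separated by at most `max_gap` nt form one (maximal) cluster.
#'
#' @param mapped mapped-read table from [map_reads_exact()].
#' @param max_gap maximum nt between neighbouring read intervals (default 10).
#' @return the table with a `cluster_id` column; clusters are numbered by
#'   genomic order.
#' @export
cluster_by_position <- function(mapped, max_gap = 10) {
  if (nrow(mapped) == 0) {
    mapped$cluster_id <- character(0)
    return(mapped)
  }
  mapped <- mapped[order(mapped$chrom, mapped$strand, mapped$start,
                         mapped$end), , drop = FALSE]
  cid <- integer(nrow(mapped))
  cur <- 0L
  cur_end <- -Inf; cur_key <- ""
  for (k in seq_len(nrow(mapped))) {
    key <- paste(mapped$chrom[k], mapped$strand[k])
    if (key != cur_key || mapped$start[k] - cur_end - 1L > max_gap) {
      cur <- cur + 1L
      cur_key <- key
      cur_end <- mapped$end[k]
    } else {
      cur_end <- max(cur_end, mapped$end[k])
    }
    cid[k] <- cur
  }
  mapped$cluster_id <- sprintf("cl%03d", cid)
  rownames(mapped) <- NULL
  mapped
}

#' Extend a read cluster into a putative precursor locus
#'
#' The cluster span is widened by `flank` nt on both sides (clamped at the
#' chromosome ends) and the strand-adjusted genomic sequence extracted. A
#' single 22 nt read away from the edges yields a 222 nt precursor with the
#' read at offset 100 (100 nt of flank precede it).
#'
#' @param cluster mapped-read rows of one cluster (same chrom/strand).
#' @param genome named character vector of chromosomes.
#' @param flank extension on each side (default 100 nt).
#' @param candidate_id identifier for the locus.
#' @return a `candidate_locus`: list with `candidate_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `precursor_sequence` and `reads`
#'   (per read: genomic interval, `offset` = nt preceding the read within the
#'   precursor, and 1-based `prec_start`/`prec_end` positions).
#' @export
extend_cluster <- function(cluster, genome, flank = 100,
                           candidate_id = cluster$cluster_id[1]) {
  if (nrow(cluster) == 0) stopf("cluster is empty")
  chrom <- cluster$chrom[1]; strand <- cluster$strand[1]
  if (any(cluster$chrom != chrom) || any(cluster$strand != strand)) {
    stopf("cluster mixes chromosomes or strands")
  }
  chrom_seq <- genome[[chrom]]
  chrom_len <- nchar(chrom_seq)
  start <- max(1L, as.integer(min(cluster$start)) - as.integer(flank))
  end <- min(chrom_len, as.integer(max(cluster$end)) + as.integer(flank))
  seq <- substr(chrom_seq, start, end)
  if (strand == "-") seq <- revcomp(seq)
  reads <- cluster[, intersect(c("id", "sequence", "count", "library_id",
                                 "start", "end"), names(cluster)),
                   drop = FALSE]
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  if (strand == "+") {
    reads$offset <- reads$start - start
  } else {
    reads$offset <- end - reads$end
  }
  reads$prec_start <- reads$offset + 1L
  reads$prec_end <- reads$offset + (reads$end - reads$start + 1L)
  rownames(reads) <- NULL
  structure(list(candidate_id = candidate_id %||% "cand", chrom = chrom,
                 start = start, end = end, strand = strand,
                 precursor_sequence = seq, reads = reads,
                 genomic_context = NA_character_, merged_from = character(0)),
            class = "candidate_locus")
}

#' @export
print.candidate_locus <- function(x, ...) {
  cat(sprintf("candidate_locus %s: %s:%d-%d(%s), %d nt precursor, %d read(s)%s\n",
              x$candidate_id, x$chrom, x$start, x$end, x$strand,
              nchar(x$precursor_sequence), nrow(x$reads),
              if (length(x$merged_from)) paste0(" [merged: ",
                paste(x$merged_from, collapse = "+"), "]") else ""))
  invisible(x)
}

#' Assign genomic context to candidate loci
#'
#' Strand-aware overlap against the annotation with feature priority
#' exon > intron > intergenic; "intron" covers explicit intron features and
#' gene/mRNA bodies outside exons.
#'
#' @param candidates list of `candidate_locus` objects.
#' @param annotation a GRanges with a `type` column (GFF3 via
#'   [read_annotation()]), or NULL for all-intergenic.
#' @return the candidates, `genomic_context` filled in.
#' @export
assign_genomic_context <- function(candidates, annotation = NULL) {
  if (length(candidates) == 0) return(candidates)
  gr <- GenomicRanges::GRanges(
    vapply(candidates, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(candidates, `[[`, 1L, "start"),
                     vapply(candidates, `[[`, 1L, "end")),
    strand = vapply(candidates, `[[`, "", "strand"))
  ctx <- rep("intergenic", length(candidates))
  if (!is.null(annotation) && length(annotation) > 0) {
    type <- as.character(annotation$type)
    exon_gr <- annotation[type %in% c("exon", "CDS")]
    intron_gr <- annotation[type %in% c("intron", "gene", "mRNA", "transcript")]
    ov_ex <- GenomicRanges::countOverlaps(gr, exon_gr, ignore.strand = FALSE)
    ov_in <- GenomicRanges::countOverlaps(gr, intron_gr, ignore.strand = FALSE)
    ctx[ov_in > 0] <- "intron"
    ctx[ov_ex > 0] <- "exon"
  }
  for (k in seq_along(candidates)) candidates[[k]]$genomic_context <- ctx[k]
  candidates
}

# Count base pairs connecting two position intervals of a structure: the
# operational test for "reads cover both sides of one stem". Overlapping
# intervals cannot be two arms of a duplex and score 0 (otherwise a short
# hairpin inside a single read interval would fake two-arm support).
reads_duplex_pairs <- function(structure, a_start, a_end, b_start, b_end) {
  if (a_start <= b_end && b_start <= a_end) return(0L)
  p <- structure$pairs
  if (is.null(p) || nrow(p) == 0) return(0L)
  inA <- function(x) x >= a_start & x <= a_end
  inB <- function(x) x >= b_start & x <= b_end
  sum((inA(p[, 1]) & inB(p[, 2])) | (inB(p[, 1]) & inA(p[, 2])))
}

#' Merge adjacent candidates sharing one stem
#'
#' Two candidates on the same chromosome and strand whose intervals overlap
#' or lie within `max_separation` nt are merged when, after folding the union
#' interval, at least `min_duplex_pairs` base pairs connect one candidate's
#' reads to the other's - i.e. the original reads cover the two arms of the
#' same predicted stem. Candidates whose reads sit on the same arm stay
#' separate. Merging runs to a fixpoint and is idempotent.
#'
#' @param candidates list of `candidate_locus` objects.
#' @param genome named character vector of chromosomes.
#' @param max_separation maximum nt between candidate intervals (default 50).
#' @param min_duplex_pairs minimum read-to-read base pairs (default 5).
#' @param fold_fun folding function (default [fold_nussinov()]).
#' @return list of `candidate_locus`; merged records carry both candidates'
#'   reads (offsets recomputed on the union precursor) and their ids in
#'   `merged_from`.
#' @export
merge_adjacent_candidates <- function(candidates, genome, max_separation = 50,
                                      min_duplex_pairs = 5,
                                      fold_fun = fold_nussinov) {
  repeat {
    merged_any <- FALSE
    n <- length(candidates)
    if (n < 2) break
    ord <- order(vapply(candidates, `[[`, "", "chrom"),
                 vapply(candidates, `[[`, "", "strand"),
                 vapply(candidates, `[[`, 1L, "start"))
    candidates <- candidates[ord]
    for (a in seq_len(n - 1)) {
      ca <- candidates[[a]]; cb <- candidates[[a + 1]]
      if (ca$chrom != cb$chrom || ca$strand != cb$strand) next
      gap <- max(ca$start, cb$start) - min(ca$end, cb$end) - 1L
      if (gap > max_separation) next
      u_start <- min(ca$start, cb$start); u_end <- max(ca$end, cb$end)
      u_seq <- substr(genome[[ca$chrom]], u_start, u_end)
      if (ca$strand == "-") u_seq <- revcomp(u_seq)
      st <- fold_fun(u_seq)
      to_local <- function(cand) {
        if (cand$strand == "+") {
          cbind(cand$reads$start - u_start + 1L, cand$reads$end - u_start + 1L)
        } else {
          cbind(u_end - cand$reads$end + 1L, u_end - cand$reads$start + 1L)
        }
      }
      la <- to_local(ca); lb <- to_local(cb)
      np <- 0L
      for (i in seq_len(nrow(la))) {
        for (j in seq_len(nrow(lb))) {
          np <- max(np, reads_duplex_pairs(st, la[i, 1], la[i, 2],
                                           lb[j, 1], lb[j, 2]))
        }
      }
      if (np >= min_duplex_pairs) {
        cl <- rbind(
          cbind(ca$reads[, c("id", "sequence", "count", "library_id",
                             "start", "end")],
                chrom = ca$chrom, strand = ca$strand),
          cbind(cb$reads[, c("id", "sequence", "count", "library_id",
                             "start", "end")],
                chrom = cb$chrom, strand = cb$strand))
        mc <- extend_cluster(cl, genome, flank = 0,
                             candidate_id = paste(ca$candidate_id,
                                                  cb$candidate_id, sep = "+"))
        # the union of two already-extended loci: keep the union interval
        mc$start <- u_start; mc$end <- u_end
        mc$precursor_sequence <- u_seq
        if (mc$strand == "+") {
          mc$reads$offset <- mc$reads$start - u_start
        } else {
          mc$reads$offset <- u_end - mc$reads$end
        }
        mc$reads$prec_start <- mc$reads$offset + 1L
        mc$reads$prec_end <- mc$reads$offset +
          (mc$reads$end - mc$reads$start + 1L)
        mc$genomic_context <- if (!is.na(ca$genomic_context) &&
                                  identical(ca$genomic_context,
                                            cb$genomic_context)) {
          ca$genomic_context
        } else NA_character_
        mc$merged_from <- c(ca$merged_from %||% character(0), ca$candidate_id,
                            cb$merged_from %||% character(0), cb$candidate_id)
        candidates[[a]] <- mc
        candidates[[a + 1]] <- NULL
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  candidates
}

#' Collapse mirror-strand candidates at one locus
#'
#' A hairpin locus is strand-symmetric to exact mapping: the mature-arm read
#' also matches the star arm on the opposite strand, so one planted hairpin
#' surfaces as two reverse-complement candidates with (near-)identical
#' coordinates. Candidates on the same chromosome and opposite strands with
#' reciprocal interval overlap of at least `min_reciprocal` are collapsed to
#' one record; the plus-strand representative is kept.
#'
#' @param candidates list of `candidate_locus` objects.
#' @param min_reciprocal reciprocal-overlap fraction (default 0.9).
#' @return de-duplicated candidate list.
#' @export
dedup_mirror_candidates <- function(candidates, min_reciprocal = 0.9) {
  n <- length(candidates)
  if (n < 2) return(candidates)
  drop <- rep(FALSE, n)
  for (a in seq_len(n - 1)) {
    if (drop[a]) next
    ca <- candidates[[a]]
    for (b in (a + 1):n) {
      if (drop[b]) next
      cb <- candidates[[b]]
      if (ca$chrom != cb$chrom || ca$strand == cb$strand) next
      ov <- min(ca$end, cb$end) - max(ca$start, cb$start) + 1L
      if (ov <= 0) next
      rec <- ov / max(ca$end - ca$start + 1L, cb$end - cb$start + 1L)
      if (rec >= min_reciprocal) {
        drop[if (ca$strand == "+") b else a] <- TRUE
      }
    }
  }
  candidates[!drop]
}

#' Export candidate loci as a GRanges (for BED/GFF3 output)
#'
#' @param candidates list of `candidate_locus` objects.
#' @return GRanges with `candidate_id`, context and read-count metadata.
#' @export
candidates_to_granges <- function(candidates) {
  if (length(candidates) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    vapply(candidates, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(candidates, `[[`, 1L, "start"),
                     vapply(candidates, `[[`, 1L, "end")),
    strand = vapply(candidates, `[[`, "", "strand"))
  mcols(gr)$name <- vapply(candidates, `[[`, "", "candidate_id")
  mcols(gr)$genomic_context <- vapply(candidates, function(x)
    x$genomic_context %||% NA_character_, "")
  mcols(gr)$n_reads <- vapply(candidates, function(x) nrow(x$reads), 1L)
  mcols(gr)$score <- vapply(candidates, function(x) sum(x$reads$count), 1)
  gr
}
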