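# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: plain-R recursion, IRanges set arithmetic and a
# matrix-based Smith-Waterman stand against the C++ kernels.

# Exhaustive enumeration of all pseudoknot-free structures of a short
# sequence: returns the maximum total pair score and, among maximum-score
# structures, the maximum pair count. Exponential - keep sequences <= 18 nt.
oracle_fold <- function(seq, min_loop = 3, scores = c(GC = 3, AU = 2, GU = 1)) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  psc <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = scores[["GC"]], "AU" = scores[["AU"]],
           "GU" = scores[["GU"]], -1L)
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(c(score = 0, pairs = 0))
    best <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      p <- psc(s[i], s[k])
      if (p < 0) next
      inner <- rec(i + 1, k - 1)
      right <- if (k < j) rec(k + 1, j) else c(score = 0, pairs = 0)
      cand <- c(score = p + inner[["score"]] + right[["score"]],
                pairs = 1 + inner[["pairs"]] + right[["pairs"]])
      if (cand[["score"]] > best[["score"]] ||
          (cand[["score"]] == best[["score"]] &&
           cand[["pairs"]] > best[["pairs"]])) {
        best <- cand
      }
    }
    best
  }
  n <- length(s)
  if (n < min_loop + 2) return(c(score = 0, pairs = 0))
  rec(1, n)
}

# Interval-intersection oracle for read-overlap classification, built on
# IRanges set operations over the helix arm intervals.
oracle_overlap <- function(structure, read_start, read_end, bulge_tol = 2) {
  h <- extract_helices(structure, bulge_tol = bulge_tol)
  if (nrow(h) == 0) return("NONE")
  arms <- IRanges::reduce(IRanges::IRanges(
    start = c(h$five_start, h$three_start),
    end = c(h$five_end, h$three_end)))
  rd <- IRanges::IRanges(read_start, read_end)
  covered <- sum(IRanges::width(IRanges::intersect(rd, arms)))
  if (covered == IRanges::width(rd)) "TOTAL"
  else if (covered == 0) "NONE"
  else "PARTIAL"
}

# Plain-R Smith-Waterman (match +1 / mismatch -1 / gap -2) with traceback;
# returns the same summary the C++ kernel reports.
oracle_sw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(0L,
        H[i, j] + if (av[i] == bv[j]) match else mismatch,
        H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  best <- max(H)
  if (best == 0) {
    return(list(score = 0, matches = 0, align_len = 0,
                a_span = 0, b_span = 0))
  }
  w <- which(H == best, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
  i <- w[1] - 1L; j <- w[2] - 1L
  matches <- 0L; cols <- 0L
  ai_end <- i; bj_end <- j
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    h <- H[i + 1, j + 1]
    if (h == H[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (h == H[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    cols <- cols + 1L
  }
  list(score = best, matches = matches, align_len = cols,
       a_span = ai_end - i, b_span = bj_end - j)
}

# The 80/80 retention rule applied to an alignment summary.
oracle_retention <- function(al, qlen, slen, min_identity = 80,
                             min_coverage = 80) {
  if (al$score <= 0 || al$align_len == 0) return(FALSE)
  identity <- 100 * al$matches / al$align_len
  qcov <- 100 * al$a_span / qlen
  scov <- 100 * al$b_span / slen
  identity >= min_identity && (qcov >= min_coverage || scov >= min_coverage)
}

# Brute-force end-anchored matcher: slide the mature across every offset and
# apply the shift/mismatch budgets directly.
oracle_match <- function(read, mature, max_mismatch = 2, max_shift = 2) {
  lr <- nchar(read); lm <- nchar(mature)
  rv <- strsplit(read, "")[[1]]; mv <- strsplit(mature, "")[[1]]
  best <- -1L
  for (s in -lm:lr) {
    idx <- seq_len(lm) + s
    inside <- idx >= 1 & idx <= lr
    if (!any(inside)) next
    if (abs(s) > max_shift) next
    if (lm - sum(inside) > max_shift) next
    mm <- sum(rv[idx[inside]] != mv[inside] | rv[idx[inside]] == "N")
    if (mm <= max_mismatch && (best < 0 || mm < best)) best <- mm
  }
  best
}

# Union-find positional clustering oracle.
oracle_cluster <- function(mapped, max_gap = 10) {
  n <- nrow(mapped)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) parent[find(a)] <<- find(b)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      same <- mapped$chrom[i] == mapped$chrom[j] &&
        mapped$strand[i] == mapped$strand[j]
      if (!same) next
      gap <- max(mapped$start[i], mapped$start[j]) -
        min(mapped$end[i], mapped$end[j]) - 1L
      if (gap <= max_gap) union_(i, j)
    }
  }
  vapply(seq_len(n), find, 1L)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small, fast simulation settings shared by unit tests (the full default
# configuration is exercised in the acceptance suite).
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 20000L, n_known_mirnas = 6L, n_novel_hairpins = 2L,
         n_contaminant_loci = 4L, n_decoy_loci = 1L,
         expression_mean_per_locus = 40),
    list(...))
  do.call(sim_config, args)
}

noiseless_sim_config <- function(...) {
  args <- utils::modifyList(
    list(read_end_jitter = 0L, error_rate = 0, fixed_counts = TRUE),
    list(...))
  do.call(small_sim_config, args)
}
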