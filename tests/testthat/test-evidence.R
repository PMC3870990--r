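fake_candidate <- function(seqs, id = "cand1", reads = NULL) {
  structure(list(candidate_id = id, chrom = "chr1", start = 1L,
                 end = nchar(seqs), strand = "+", precursor_sequence = seqs,
                 reads = reads %||% data.frame(), genomic_context = NA_character_,
                 merged_from = character(0)),
            class = "candidate_locus")
}

test_that("similarity search retains by identity and either-side coverage", {
  set.seed(71)
  flank1 <- random_dna_str(100); flank2 <- random_dna_str(100)
  subject <- random_dna_str(22)
  cand <- fake_candidate(paste0(flank1, subject, flank2))
  db <- data.frame(name = "db1", type = "miRNA", sequence = subject,
                   stringsAsFactors = FALSE)
  hit <- similarity_search(cand, db)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$subject_coverage, 100)
  expect_equal(hit$identity, 100)
  expect_lt(hit$query_coverage, 80)   # subject-side coverage carried it
  # a long subject matched over only 70% identity is rejected
  sv <- strsplit(subject, "")[[1]]
  mut <- sv
  mut[seq(8, 20, by = 2)] <- vapply(mut[seq(8, 20, by = 2)], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  db70 <- data.frame(name = "db2", type = "miRNA",
                     sequence = paste(mut, collapse = ""),
                     stringsAsFactors = FALSE)
  expect_identical(nrow(similarity_search(cand, db70, max_evalue = Inf)), 0L)
  expect_error(similarity_search(cand, db[0, ]), "empty")
  db_bad <- db; db_bad$type <- ""
  expect_error(similarity_search(cand, db_bad), "type label")
})

test_that("seeded search matches exhaustive Smith-Waterman retention", {
  set.seed(72)
  agree <- 0L; n_cases <- 60L
  for (k in seq_len(n_cases)) {
    qlen <- sample(150:250, 1)
    slen <- sample(18:45, 1)
    query <- random_dna_str(qlen)
    subject <- if (runif(1) < 0.5) {
      # plant a mutated copy of the subject inside the query
      s <- substr(query, 60, 60 + slen - 1)
      sv <- strsplit(s, "")[[1]]
      nmut <- sample(0:4, 1)
      for (q in sample(length(sv), nmut)) {
        sv[q] <- sample(setdiff(c("A", "C", "G", "T"), sv[q]), 1)
      }
      paste(sv, collapse = "")
    } else {
      random_dna_str(slen)
    }
    cand <- fake_candidate(query)
    db <- data.frame(name = "s", type = "miRNA", sequence = subject,
                     stringsAsFactors = FALSE)
    got <- nrow(similarity_search(cand, db, max_evalue = Inf)) > 0
    want <- oracle_retention(oracle_sw(query, subject), qlen, slen)
    expect_identical(got, want)
    agree <- agree + as.integer(got == want)
  }
  expect_identical(agree, n_cases)
})

test_that("false-positive exclusion applies one prioritized reason", {
  set.seed(73)
  g <- random_dna_str(3000)
  mk_cand <- function(id, start) {
    extend_cluster(
      data.frame(id = paste0(id, "_r"), sequence = substr(g, start, start + 21),
                 count = 20L, library_id = "x", chrom = "chr1", start = start,
                 end = start + 21L, strand = "+", cluster_id = id,
                 stringsAsFactors = FALSE),
      c(chr1 = g), candidate_id = id)
  }
  c_ex <- mk_cand("c_ex", 501)
  c_sno <- mk_cand("c_sno", 1201)
  c_ok <- mk_cand("c_ok", 1901)
  c_trna <- mk_cand("c_trna", 2501)
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(490, 2490), c(650, 2650)), strand = "+",
    type = c("exon", "tRNA"))
  hits <- data.frame(
    candidate_id = c("c_sno", "c_ok", "c_ex"),
    subject_type = c("snoRNA", "unclassified RNA", "snoRNA"),
    stringsAsFactors = FALSE)
  ex <- exclude_false_positives(list(c_ex, c_sno, c_ok, c_trna),
                                annotation = ann, similarity_hits = hits)
  expect_identical(ex$excluded$reason[ex$excluded$candidate_id == "c_ex"],
                   "exon_overlap")   # exon wins over its ncRNA hit
  expect_identical(ex$excluded$reason[ex$excluded$candidate_id == "c_sno"],
                   "non_miRNA_ncRNA_match")
  expect_identical(ex$excluded$reason[ex$excluded$candidate_id == "c_trna"],
                   "tRNA_call")
  kept_ids <- vapply(ex$kept, `[[`, "", "candidate_id")
  expect_identical(kept_ids, "c_ok")  # miRNA/unclassified hits never exclude
  expect_identical(length(ex$kept) + nrow(ex$excluded), 4L)
})

test_that("external evidence parsers enforce cutoffs and report bad lines", {
  tbl <- c(
    "#target name accession query accession mdl mdl_from mdl_to seq_from seq_to strand trunc pass gc bias score evalue inc description",
    "cand04 - MIR245 RF00816 cm 1 85 97 182 + no 1 0.45 0.0 29.76 1.2e-06 ! -",
    "cand09 - mir-450 RF00708 cm 1 80 112 32 - no 1 0.44 0.0 30.40 2.0e-06 ! -",
    "cand10 - mir-689 RF00871 cm 1 75 17 91 + no 1 0.50 0.0 24.90 1.0e-03 ! -")
  path <- withr::local_tempfile(fileext = ".tblout")
  writeLines(tbl, path)
  fh <- parse_infernal_tblout(path)
  expect_identical(fh$candidate_id, c("cand04", "cand09"))
  expect_equal(fh$bit_score, c(29.76, 30.40))    # 24.90 is below cutoff 25
  expect_identical(fh$start[2], 32L)             # minus-strand normalized
  expect_identical(fh$end[2], 112L)
  expect_identical(fh$strand[2], "-")
  writeLines(c(tbl[2], "cand bad row"), path)
  expect_error(parse_infernal_tblout(path), "line 2")

  sc <- c("cand01 0.67", "cand02 0.69", "cand03 0.75")
  writeLines(sc, path)
  hh <- read_hhmmir_scores(path)
  expect_equal(hh$score, c(0.67, 0.69, 0.75))
  expect_identical(hh$passes_cutoff, c(FALSE, FALSE, TRUE))
  writeLines(c(sc, "cand04 notanumber"), path)
  expect_error(read_hhmmir_scores(path), "line 4")
})

test_that("the ab-initio score separates hairpins from shuffles and is monotone", {
  set.seed(74)
  arm <- random_dna_str(21)
  prec <- paste0(random_dna_str(100), arm, random_dna_str(12),
                 revcomp(arm), random_dna_str(100))
  st <- fold_nussinov(prec)
  f <- hairpin_features(st, 101, 121)
  expect_gte(score_abinitio(f), 0.71)
  below <- 0L
  for (k in 1:60) {
    sh <- srnamine:::dinucleotide_shuffle(prec)
    stn <- fold_nussinov(sh)
    if (score_abinitio(hairpin_features(stn, 101, 121)) < 0.71) {
      below <- below + 1L
    }
  }
  expect_gte(below / 60, 0.9)
  # monotone nondecreasing in paired_fraction, other features fixed
  f_lo <- f; f_lo$paired_fraction <- 0.3
  f_hi <- f; f_hi$paired_fraction <- 0.9
  expect_lte(score_abinitio(f_lo), score_abinitio(f_hi))
})

test_that("mature/star proposals follow the 2 nt overhang duplex arithmetic", {
  set.seed(75)
  arm <- random_dna_str(20)
  prec <- paste0(arm, random_dna_str(8), revcomp(arm))
  st <- fold_nussinov(prec)
  cand <- fake_candidate(prec, reads = data.frame(
    id = "r1", sequence = arm, count = 30L, library_id = "x",
    offset = 0L, prec_start = 1L, prec_end = 20L, stringsAsFactors = FALSE))
  pr <- propose_mature(cand, st)
  expect_identical(pr$proposal, c("read", "star"))
  # expected star from the pairing arithmetic on the known structure
  partner <- integer(nchar(prec))
  partner[st$pairs[, 1]] <- st$pairs[, 2]
  partner[st$pairs[, 2]] <- st$pairs[, 1]
  partners <- partner[1:20]; partners <- partners[partners > 0]
  expect_identical(pr$start[2], min(partners) + 2L)
  expect_identical(pr$end[2], min(nchar(prec), max(partners) + 2L))
  expect_identical(pr$arm, c("5p", "3p"))
  # duplex proposals occupy disjoint positions
  expect_true(pr$end[1] < pr$start[2] || pr$end[2] < pr$start[1])
  # a read confined to the loop proposes nothing (all-A loop cannot pair)
  prec_a <- paste0(arm, strrep("A", 8), revcomp(arm))
  st_a <- fold_nussinov(prec_a)
  cand_loop <- fake_candidate(prec_a, reads = data.frame(
    id = "r2", sequence = substr(prec_a, 22, 27), count = 5L,
    library_id = "x", offset = 21L, prec_start = 22L, prec_end = 27L,
    stringsAsFactors = FALSE))
  expect_identical(nrow(propose_mature(cand_loop, st_a)), 0L)
})

test_that("verdict tiers are deterministic and monotone in the evidence", {
  set.seed(76)
  arm <- random_dna_str(20)
  prec <- paste0(random_dna_str(100), arm, random_dna_str(10),
                 revcomp(arm), random_dna_str(100))
  st <- fold_nussinov(prec)
  reads <- data.frame(id = "r1", sequence = arm, count = 30L,
                      library_id = "x", offset = 100L, prec_start = 101L,
                      prec_end = 120L, stringsAsFactors = FALSE)
  cand <- fake_candidate(prec, reads = reads)
  sim_hit <- data.frame(candidate_id = "cand1", subject_id = "s",
                        subject_type = "miRNA", score = 20, identity = 100,
                        query_coverage = 10, subject_coverage = 95,
                        evalue_proxy = 1e-9, evalue_ok = TRUE,
                        stringsAsFactors = FALSE)
  fam_hit <- data.frame(candidate_id = "cand1", family_id = "MIR245",
                        family_acc = "RF00816", bit_score = 29.76,
                        start = 95L, end = 180L, strand = "+",
                        stringsAsFactors = FALSE)
  tier <- function(...) integrate_evidence(cand, st, ...)$verdict_tier
  # no channels, read in stem: weak
  expect_identical(tier(), "weak")
  # one channel + read in stem: supported
  expect_identical(tier(similarity_hits = sim_hit), "supported")
  expect_identical(tier(abinitio_score = 0.9), "supported")
  # sub-threshold ab-initio is recorded, not a positive channel
  expect_identical(tier(abinitio_score = 0.67), "weak")
  # family hit covering the read anchors a strong verdict
  expect_identical(tier(family_hits = fam_hit), "strong")
  # exclusion dominates everything
  expect_identical(tier(family_hits = fam_hit,
                        excluded_reason = "exon_overlap"), "excluded")
  # merged two-arm candidates are strong with no other channel
  cand_m <- cand; cand_m$merged_from <- c("a", "b")
  expect_identical(integrate_evidence(cand_m, st)$verdict_tier, "strong")
  # monotonicity: adding a positive channel never lowers the tier
  rank <- c(weak = 1, supported = 2, strong = 3)
  base_args <- list(list(), list(similarity_hits = sim_hit),
                    list(abinitio_score = 0.9),
                    list(similarity_hits = sim_hit, abinitio_score = 0.9),
                    list(family_hits = fam_hit),
                    list(family_hits = fam_hit, similarity_hits = sim_hit))
  tiers <- vapply(base_args, function(a) do.call(tier, a), "")
  for (i in seq_along(base_args)) {
    for (j in seq_along(base_args)) {
      sub <- all(names(base_args[[i]]) %in% names(base_args[[j]]))
      if (sub && i != j) expect_lte(rank[tiers[i]], rank[tiers[j]])
    }
  }
})

test_that("a read in the loop with one channel is weak, per the NONE rule", {
  set.seed(77)
  arm <- random_dna_str(20)
  loop <- random_dna_str(12)
  prec <- paste0(arm, loop, revcomp(arm))
  st <- fold_nussinov(prec)
  # place the "read" inside the loop
  cand <- fake_candidate(prec, reads = data.frame(
    id = "r1", sequence = substr(prec, 23, 30), count = 20L,
    library_id = "x", offset = 22L, prec_start = 23L, prec_end = 30L,
    stringsAsFactors = FALSE))
  rec <- integrate_evidence(cand, st, abinitio_score = 0.9)
  if (rec$read_overlap == "NONE") {
    expect_identical(rec$verdict_tier, "weak")
  } else {
    expect_identical(rec$verdict_tier, "supported")
  }
})
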