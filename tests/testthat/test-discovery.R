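test_that("discovery read selection applies the length and copy filters", {
  reads <- data.frame(
    id = c("a", "b", "c", "d"),
    sequence = c(strrep("A", 22), strrep("C", 35), strrep("G", 22),
                 strrep("T", 34)),
    count = c(50L, 50L, 3L, 10L), library_id = "x",
    stringsAsFactors = FALSE)
  sel <- select_discovery_reads(reads)
  expect_identical(sel$id, c("a", "d"))   # 35-mer out, 3 copies out, 10 in
  strict <- select_discovery_reads(reads, strict_copies = TRUE)
  expect_identical(strict$id, "a")        # inclusive vs strict threshold
})

test_that("exact mapping reports both strands and logs the rest", {
  set.seed(55)
  g <- random_dna_str(4000)
  r1 <- substr(g, 501, 522)
  r2 <- revcomp(substr(g, 1201, 1222))     # minus-strand planting
  reads <- data.frame(id = c("p", "m", "absent"),
                      sequence = c(r1, r2, strrep("ACGT", 6)),
                      count = 20L, library_id = "x", stringsAsFactors = FALSE)
  mp <- map_reads_exact(reads, c(chr1 = g))
  p <- mp$mapped[mp$mapped$id == "p", ]
  expect_identical(nrow(p), 1L)
  expect_identical(c(p$start, p$end, p$strand), c("501", "522", "+"))
  m <- mp$mapped[mp$mapped$id == "m", ]
  expect_identical(m$strand, "-")
  expect_identical(revcomp(substr(g, m$start, m$end)), r2)
  expect_identical(mp$dropped$id, "absent")
  expect_identical(mp$dropped$reason, "no_placement")
  # a read planted at six loci exceeds the placement cap
  g6 <- paste0(g, strrep(paste0(r1, strrep("T", 30)), 6))
  mp6 <- map_reads_exact(reads[1, ], c(chr1 = g6), max_loci = 5)
  expect_identical(mp6$dropped$reason, "multimapped")
})

test_that("positional clustering is maximal, transitive and idempotent", {
  mk <- function(start, end, strand = "+", chrom = "chr1") {
    data.frame(id = sprintf("r%d", seq_along(start)), sequence = "A",
               count = 20L, library_id = "x", chrom = chrom, start = start,
               end = end, strand = strand, stringsAsFactors = FALSE)
  }
  same <- cluster_by_position(mk(c(100, 100), c(121, 121)))
  expect_identical(length(unique(same$cluster_id)), 1L)
  far <- cluster_by_position(mk(c(100, 1100), c(121, 1121)))
  expect_identical(length(unique(far$cluster_id)), 2L)
  # chain a-b-c with gaps of 5 joins transitively
  chain <- cluster_by_position(mk(c(100, 127, 154), c(121, 148, 175)))
  expect_identical(length(unique(chain$cluster_id)), 1L)
  # agreement with a union-find oracle on random layouts
  set.seed(56)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    st <- sort(sample(1:2000, n))
    tbl <- mk(st, st + sample(18:24, n, replace = TRUE),
              strand = sample(c("+", "-"), n, replace = TRUE))
    got <- cluster_by_position(tbl)
    want <- oracle_cluster(got)   # same row order as clustered output
    expect_identical(length(unique(got$cluster_id)), length(unique(want)))
    expect_true(all(tapply(want, got$cluster_id,
                           function(x) length(unique(x))) == 1))
  }
  twice <- cluster_by_position(chain)
  expect_identical(twice$cluster_id, chain$cluster_id)
})

test_that("cluster extension yields the documented precursor arithmetic", {
  set.seed(57)
  g <- random_dna_str(3000)
  mk <- function(start, end, strand = "+") {
    data.frame(id = "r1", sequence = if (strand == "+")
      substr(g, start, end) else revcomp(substr(g, start, end)),
      count = 20L, library_id = "x", chrom = "chr1", start = start,
      end = end, strand = strand, cluster_id = "cl1",
      stringsAsFactors = FALSE)
  }
  # a 22 nt read away from the edges: 222 nt precursor, read offset 100
  cand <- extend_cluster(mk(1001, 1022), c(chr1 = g))
  expect_identical(nchar(cand$precursor_sequence), 222L)
  expect_identical(cand$reads$offset, 100L)
  expect_identical(cand$reads$prec_start, 101L)
  # a read starting 40 nt into the chromosome: clamped flank, offset 40
  edge <- extend_cluster(mk(41, 62), c(chr1 = g))
  expect_identical(edge$start, 1L)
  expect_identical(edge$reads$offset, 40L)
  # minus-strand extraction is the reverse complement of the plus one
  minus <- extend_cluster(mk(1001, 1022, "-"), c(chr1 = g))
  plus <- extend_cluster(mk(1001, 1022), c(chr1 = g))
  expect_identical(minus$precursor_sequence, revcomp(plus$precursor_sequence))
  expect_identical(minus$reads$offset, 100L)
  expect_identical(substr(minus$precursor_sequence, minus$reads$prec_start,
                          minus$reads$prec_end),
                   minus$reads$sequence)
})

test_that("adjacent candidates merge only across the two arms of one stem", {
  set.seed(58)
  g <- random_dna_str(6000)
  arm <- random_dna_str(22)
  hp <- plant_hairpin(g, arm, loop_len = 14, position = 2001)
  g <- hp$genome
  tr <- hp$truth
  mk <- function(id, start, end, seqs) {
    data.frame(id = id, sequence = seqs, count = 30L, library_id = "x",
               chrom = "chr1", start = start, end = end, strand = "+",
               cluster_id = id, stringsAsFactors = FALSE)
  }
  c5 <- extend_cluster(mk("c5", tr$mature_start, tr$mature_end, arm),
                       c(chr1 = g), candidate_id = "c5")
  c3 <- extend_cluster(mk("c3", tr$star_start, tr$star_end, tr$star_seq),
                       c(chr1 = g), candidate_id = "c3")
  merged <- merge_adjacent_candidates(list(c5, c3), c(chr1 = g))
  expect_length(merged, 1L)
  expect_identical(sort(merged[[1]]$merged_from), c("c3", "c5"))
  expect_identical(nrow(merged[[1]]$reads), 2L)
  # merging is idempotent
  again <- merge_adjacent_candidates(merged, c(chr1 = g))
  expect_length(again, 1L)
  # same-arm neighbours stay separate: two copies of the same arm sequence
  g2 <- random_dna_str(6000)
  substr(g2, 3001, 3022) <- arm
  substr(g2, 3051, 3072) <- arm
  a1 <- extend_cluster(mk("a1", 3001, 3022, arm), c(chr1 = g2),
                       candidate_id = "a1")
  a2 <- extend_cluster(mk("a2", 3051, 3072, arm), c(chr1 = g2),
                       candidate_id = "a2")
  expect_length(merge_adjacent_candidates(list(a1, a2), c(chr1 = g2)), 2L)
  # distant candidates are never considered
  b2 <- extend_cluster(mk("b2", 5501, 5522, substr(g2, 5501, 5522)),
                       c(chr1 = g2), candidate_id = "b2")
  expect_length(merge_adjacent_candidates(list(a1, b2), c(chr1 = g2)), 2L)
})

test_that("candidate GFF3 export round-trips intervals exactly", {
  set.seed(59)
  g <- random_dna_str(2000)
  cand <- extend_cluster(
    data.frame(id = "r1", sequence = substr(g, 901, 922), count = 15L,
               library_id = "x", chrom = "chr1", start = 901, end = 922,
               strand = "-", cluster_id = "cl1", stringsAsFactors = FALSE),
    c(chr1 = g))
  gr <- candidates_to_granges(list(cand))
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$name
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(gr, path)
  back <- read_annotation(path)
  expect_identical(BiocGenerics::start(back), BiocGenerics::start(gr))
  expect_identical(BiocGenerics::end(back), BiocGenerics::end(gr))
  expect_identical(as.character(BiocGenerics::strand(back)),
                   as.character(BiocGenerics::strand(gr)))
})

test_that("a noiseless fixture yields one candidate per planted novel locus", {
  cfg <- noiseless_sim_config(seed = 61)
  sim <- build_simulation(cfg)
  rd <- simulate_reads(sim)
  pc <- pipeline_config(seed = 1)
  qr <- run_quantify(pc, inputs = list(reads = rd$reads,
                                       reference = sim$mature_reference,
                                       contaminants = sim$contaminants))
  dr <- run_discover(pc, qr, inputs = list(genome = sim$genome,
                                           ncrna_db = sim$ncrna_db,
                                           annotation = sim$annotation))
  novel <- sim$truth[sim$truth$class == "novel_hairpin" &
                       sim$truth$arm == "5p", ]
  # exactly one (possibly merged) candidate covers each planted precursor
  for (k in seq_len(nrow(novel))) {
    hit <- vapply(dr$candidates, function(cand)
      cand$start <= novel$precursor_start[k] &&
        cand$end >= novel$precursor_end[k], TRUE)
    expect_identical(sum(hit), 1L)
  }
  # count conservation: every selected read lands in a pre-exclusion
  # candidate or in the dropped log, and each placement is in one candidate
  placed <- unlist(lapply(dr$all_candidates, function(cand) cand$reads$id))
  expect_setequal(c(placed, dr$dropped$id), dr$selected$id)
  n_place <- table(placed)
  # hairpin reads legitimately map to both strands of the stem (two
  # placements); nothing exceeds the placement cap
  expect_true(all(n_place <= dr$config$max_loci))
})
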