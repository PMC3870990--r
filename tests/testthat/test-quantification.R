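make_reference <- function() {
  data.frame(
    mature_name = c("mir-A", "mir-B", "hsa-mir-103a", "hsa-mir-103a"),
    precursor_id = c("mir-A", "mir-B", "hsa-mir-103a-1", "hsa-mir-103a-2"),
    family_key = c("mir-A", "mir-B", "hsa-mir-103a", "hsa-mir-103a"),
    sequence = c("ACGTACGTACGTACGTACGT",
                 "TTTTGGGGCCCCAAAATTTT",
                 "AGCAGCATTGTACAGGGCTATGA",
                 "AGCAGCATTGTACAGGGCTATGA"),
    stringsAsFactors = FALSE)
}

test_that("contaminant filtering removes substring matches per class", {
  db <- data.frame(name = c("rrna1", "trna1"), class = c("rRNA", "tRNA"),
                   sequence = c("AAACCCGGGTTTAAACCCGGGTTTAAACCC",
                                "GCGCGCATATATGCGCGCATATAT"),
                   stringsAsFactors = FALSE)
  reads <- data.frame(id = c("r1", "r2"),
                      sequence = c("CCCGGGTTTAAACCCGG",   # rRNA substring
                                   "ACGTACGTACGTACGTA"),  # matches nothing
                      count = c(5L, 7L), library_id = "lib1",
                      stringsAsFactors = FALSE)
  fc <- filter_contaminants(reads, db)
  expect_identical(fc$removed$id, "r1")
  expect_identical(fc$removed$class, "rRNA")
  expect_identical(fc$kept$id, "r2")
  expect_identical(sum(fc$kept$count) + sum(fc$removed$count),
                   sum(reads$count))
  db_bad <- db; db_bad$class[1] <- ""
  expect_error(filter_contaminants(reads, db_bad), "class label")
})

test_that("mature matching agrees with the brute-force anchored oracle", {
  ref <- make_reference()
  # identical read: one locus per matching sequence
  hits <- match_mature("ACGTACGTACGTACGTACGT", ref)
  expect_identical(hits$mature_name, "mir-A")
  expect_identical(hits$mismatches, 0L)
  # three substitutions exceed the budget of 2 everywhere
  r3 <- "ACCTACGAACGTACGTACGA"
  expect_identical(nrow(match_mature(r3, ref,
                                     max_mismatch = 2, max_shift = 0)), 0L)
  # family twins produce two hits
  hits2 <- match_mature("AGCAGCATTGTACAGGGCTATGA", ref)
  expect_identical(nrow(hits2), 2L)
  expect_identical(unique(hits2$family_key), "hsa-mir-103a")
  # property: agreement with the exhaustive scan, and monotonicity in the
  # mismatch budget
  set.seed(42)
  for (k in 1:60) {
    ref_k <- data.frame(mature_name = "m", precursor_id = "m",
                        family_key = "m",
                        sequence = random_dna_str(sample(18:24, 1)),
                        stringsAsFactors = FALSE)
    read <- random_dna_str(sample(18:30, 1))
    if (runif(1) < 0.5) {
      # derive the read from the reference with jitter + errors
      s <- ref_k$sequence
      s <- substr(s, 1 + sample(0:2, 1), nchar(s) - sample(0:2, 1))
      p <- sample(nchar(s), sample(0:3, 1))
      sv <- strsplit(s, "")[[1]]
      for (q in p) sv[q] <- sample(c("A", "C", "G", "T"), 1)
      read <- paste0(paste(sv, collapse = ""),
                     random_dna_str(sample(0:2, 1)))
      if (nchar(read) < 15) read <- paste0(read, random_dna_str(15))
    }
    got <- match_mature(read, ref_k)
    want <- oracle_match(read, ref_k$sequence)
    if (want < 0) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$mismatches, want)
    }
    n0 <- nrow(match_mature(read, ref_k, max_mismatch = 0))
    n2 <- nrow(match_mature(read, ref_k, max_mismatch = 2))
    n4 <- nrow(match_mature(read, ref_k, max_mismatch = 4))
    expect_true(n0 <= n2 && n2 <= n4)
  }
  expect_error(match_mature("ACGTACGT", ref), ">= 15 nt")
})

test_that("multi-hit collapse follows the 5-hit single-family rule", {
  hit <- function(mature, prec, fam) {
    data.frame(mature_name = mature, precursor_id = prec, family_key = fam,
               mismatches = 0L, stringsAsFactors = FALSE)
  }
  none <- assign_read(data.frame(mature_name = character(0),
                                 precursor_id = character(0),
                                 family_key = character(0),
                                 mismatches = integer(0)))
  expect_identical(none$status, "unmatched")
  one <- assign_read(hit("mir-X", "mir-X", "mir-X"))
  expect_identical(one$status, "assigned")
  expect_identical(one$label, "mir-X")
  # the two-locus family collapses to the family key
  fam2 <- assign_read(rbind(hit("hsa-mir-103a", "hsa-mir-103a-1", "hsa-mir-103a"),
                            hit("hsa-mir-103a", "hsa-mir-103a-2", "hsa-mir-103a")))
  expect_identical(fam2$status, "assigned")
  expect_identical(fam2$label, "hsa-mir-103a")
  # five hits in one family pass; six are discarded
  h5 <- do.call(rbind, lapply(1:5, function(i)
    hit("m", sprintf("fam-%d", i), "fam")))
  expect_identical(assign_read(h5)$status, "assigned")
  expect_identical(assign_read(h5)$label, "fam")
  h6 <- do.call(rbind, lapply(1:6, function(i)
    hit("m", sprintf("fam-%d", i), "fam")))
  expect_identical(assign_read(h6)$status, "discarded_multihit")
  # two families are discarded even with only two hits
  h2f <- rbind(hit("a", "a-1", "fam-a"), hit("b", "b-1", "fam-b"))
  expect_identical(assign_read(h2f)$status, "discarded_multihit")
  # cap applied on families when requested
  expect_identical(assign_read(h6, cap_on = "families")$status, "assigned")
})

test_that("quantification is additive and the ledger conserves copies", {
  ref <- make_reference()
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    sequence = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGTA",
                 "GGGGGGGGGGGGGGGGGGGG"),
    count = c(3L, 4L, 9L), library_id = "lib1", stringsAsFactors = FALSE)
  prof <- quantify(reads, ref)
  expect_identical(prof$entries$raw_count[prof$entries$label == "mir-A"], 7L)
  expect_identical(sum(prof$ledger[c("contaminant", "unmatched",
                                     "discarded_multihit", "assigned")]),
                   prof$ledger[["total"]])
  expect_identical(prof$unmatched$id, "r3")
})

test_that("a noiseless fixture is recovered label-exactly with its contaminants", {
  cfg <- noiseless_sim_config(seed = 33)
  sim <- build_simulation(cfg)
  rd <- simulate_reads(sim)
  lib <- cfg$libraries[1]
  prof <- quantify(rd$reads[rd$reads$library_id == lib, ],
                   sim$mature_reference, contaminant_db = sim$contaminants,
                   library_id = lib)
  # expected per-label counts from the recorded draws
  tr <- sim$truth
  dr <- rd$draws[rd$draws$library_id == lib, ]
  dr$label <- tr$label[match(dr$unit_id, tr$unit_id)]
  dr$class <- tr$class[match(dr$unit_id, tr$unit_id)]
  want <- stats::aggregate(count ~ label, data = dr[dr$class == "known_mirna", ],
                           FUN = sum)
  got <- prof$entries[match(want$label, prof$entries$label), ]
  expect_identical(got$raw_count, want$count)
  # all planted contaminant copies (and only those) are filtered
  expect_identical(prof$ledger[["contaminant"]],
                   sum(dr$count[dr$class == "contaminant"]))
})
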