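# Synthetic small-RNA study generator: a toy genome with planted known-miRNA
# hairpins (some as two-locus families), novel two-arm hairpins, contaminant
# loci and unstructured decoys, plus simulated reads for two libraries with
# planted fold-changes and a full ground-truth table. Everything is
# deterministic for a fixed seed.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: a 50 kb genome, 20
#' known miRNA genes (a fifth of them as two-locus families sharing one mature
#' sequence), 5 novel two-arm hairpins, 8 contaminant loci cycling
#' rRNA/tRNA/repeat/adapter, 3 unstructured decoy loci, mean expression 100
#' reads per locus and library, a planted 4-fold change for 30% of known genes
#' between the two libraries, 0-1 nt end jitter and a 0.1% per-base error.
#'
#' @param genome_length toy genome size (nt).
#' @param n_known_mirnas number of known miRNA genes (with reference entries).
#' @param n_novel_hairpins number of planted novel hairpins (no reference).
#' @param n_contaminant_loci number of rRNA/tRNA/repeat/adapter loci.
#' @param n_decoy_loci unstructured loci emitting abundant reads; negatives
#'   for the discovery branch.
#' @param mature_length_range mature miRNA length range (nt).
#' @param loop_length_range hairpin loop length range (nt).
#' @param arm_mismatch_rate per-base mismatch rate on the 3' arm of planted
#'   hairpins (0 = perfect stems).
#' @param expression_mean_per_locus mean reads per locus per library.
#' @param read_end_jitter maximum nt trimmed from each read end (uniform
#'   0..jitter; supported up to 2).
#' @param error_rate per-base substitution probability on reads.
#' @param libraries character vector of library ids (two for DE analysis).
#' @param de_fraction fraction of known genes with a planted fold change.
#' @param de_fold planted fold change between the two libraries.
#' @param dominant_locus_factor expression multiplier for the last known
#'   gene, planted equally in all libraries. Real small RNA libraries are
#'   dominated by a few ubiquitous molecules (miR-21-like); a stable dominant
#'   locus reproduces that shape and anchors max-normalization.
#' @param family_duplicate_fraction fraction of known genes planted at two
#'   genomic loci (miR-103a-style families).
#' @param fixed_counts if TRUE, per-locus counts are exactly the mean (no
#'   Poisson sampling); for exact-count tests.
#' @param seed RNG seed; fixed seed gives byte-identical fixtures.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(genome_length = 50000L,
                       n_known_mirnas = 20L,
                       n_novel_hairpins = 5L,
                       n_contaminant_loci = 8L,
                       n_decoy_loci = 3L,
                       mature_length_range = c(19L, 22L),
                       loop_length_range = c(8L, 15L),
                       arm_mismatch_rate = 0,
                       expression_mean_per_locus = 100,
                       read_end_jitter = 1L,
                       error_rate = 0.001,
                       libraries = c("libA", "libB"),
                       de_fraction = 0.3,
                       de_fold = 4,
                       dominant_locus_factor = 10,
                       family_duplicate_fraction = 0.2,
                       fixed_counts = FALSE,
                       seed = 42L) {
  assert_scalar_count(genome_length, "genome_length", min = 1)
  for (nm in c("n_known_mirnas", "n_novel_hairpins", "n_contaminant_loci",
               "n_decoy_loci")) {
    assert_scalar_count(get(nm), nm, min = 0)
  }
  for (r in c(arm_mismatch_rate, error_rate, de_fraction,
              family_duplicate_fraction)) {
    if (r < 0 || r > 1) stopf("rates must be in [0, 1]")
  }
  if (read_end_jitter < 0) stopf("read_end_jitter must be >= 0")
  cfg <- list(genome_length = as.integer(genome_length),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_hairpins = as.integer(n_novel_hairpins),
              n_contaminant_loci = as.integer(n_contaminant_loci),
              n_decoy_loci = as.integer(n_decoy_loci),
              mature_length_range = as.integer(mature_length_range),
              loop_length_range = as.integer(loop_length_range),
              arm_mismatch_rate = arm_mismatch_rate,
              expression_mean_per_locus = expression_mean_per_locus,
              read_end_jitter = as.integer(read_end_jitter),
              error_rate = error_rate,
              libraries = libraries,
              de_fraction = de_fraction,
              de_fold = de_fold,
              dominant_locus_factor = dominant_locus_factor,
              family_duplicate_fraction = family_duplicate_fraction,
              fixed_counts = isTRUE(fixed_counts),
              seed = as.integer(seed))
  n_dup <- floor(cfg$n_known_mirnas * cfg$family_duplicate_fraction)
  n_slots <- cfg$n_known_mirnas + n_dup + cfg$n_novel_hairpins +
    cfg$n_contaminant_loci + cfg$n_decoy_loci
  if (n_slots > 0 && cfg$genome_length < n_slots * 300L + 400L) {
    stopf("genome_length %d too small for %d planted loci (need >= %d)",
          cfg$genome_length, n_slots, n_slots * 300L + 400L)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random genome sequence
#'
#' @param config a [sim_config()] (`genome_length`, `seed` used).
#' @return a single uppercase DNA string of exactly `genome_length` nt.
#' @export
generate_genome <- function(config) {
  if (config$genome_length <= 0) stopf("genome_length must be positive")
  with_seed(config$seed, random_dna(config$genome_length))
}

# Substitute bases at `rate`; each hit base becomes a different random base.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (k in hit) {
    ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1L)
  }
  paste(ch, collapse = "")
}

#' Plant a hairpin construct in a genome
#'
#' Overwrites the genome at `position` with mature arm + loop + reverse
#' complement of the arm (per-base mismatches on the 3' arm at
#' `arm_mismatch_rate`), so that folding the construct recovers a stem
#' carrying the mature sequence. On the minus strand the genome carries the
#' reverse complement of the whole construct. Genome length is unchanged.
#'
#' @param genome single DNA string.
#' @param mature_seq mature (5' arm) DNA sequence, >= 15 nt.
#' @param loop_len loop length (nt); loop bases are drawn at random unless
#'   `loop_seq` is given.
#' @param position 1-based start of the construct in the genome.
#' @param strand `"+"` or `"-"`.
#' @param arm_mismatch_rate per-base mismatch rate on the complementary arm.
#' @param loop_seq optional explicit loop sequence (overrides `loop_len`).
#' @return list with `genome` (modified), and `truth` - a one-row data.frame
#'   with the precursor and mature intervals (1-based inclusive), strand and
#'   sequences (`mature_seq`, `star_seq`: the 3' arm small RNA as sequenced).
#' @export
plant_hairpin <- function(genome, mature_seq, loop_len, position, strand = "+",
                          arm_mismatch_rate = 0, loop_seq = NULL) {
  mature_seq <- toupper(mature_seq)
  la <- nchar(mature_seq)
  if (la < 15) stopf("mature_seq must be >= 15 nt (got %d)", la)
  if (is.null(loop_seq)) loop_seq <- random_dna(loop_len)
  loop_len <- nchar(loop_seq)
  arm3 <- mutate_sequence(revcomp(mature_seq), arm_mismatch_rate)
  construct <- paste0(mature_seq, loop_seq, arm3)
  L <- nchar(construct)
  glen <- nchar(genome)
  if (position < 1 || position + L - 1 > glen) {
    stopf("construct [%d, %d] out of genome range [1, %d]",
          position, position + L - 1, glen)
  }
  planted <- if (strand == "+") construct else revcomp(construct)
  substr(genome, position, position + L - 1) <- planted
  if (strand == "+") {
    mat_start <- position; mat_end <- position + la - 1
    star_start <- position + la + loop_len; star_end <- position + L - 1
  } else {
    mat_start <- position + L - la; mat_end <- position + L - 1
    star_start <- position; star_end <- position + la - 1
  }
  truth <- data.frame(
    chrom = "chr1", strand = strand,
    precursor_start = position, precursor_end = position + L - 1,
    mature_start = mat_start, mature_end = mat_end,
    star_start = star_start, star_end = star_end,
    mature_seq = mature_seq, star_seq = arm3,
    stringsAsFactors = FALSE
  )
  list(genome = genome, truth = truth)
}

# Draw a per-locus read count.
draw_count <- function(mean, fixed) {
  if (fixed) as.integer(round(mean)) else stats::rpois(1L, mean)
}

#' Assemble the full synthetic study
#'
#' Plants all loci in a fresh genome and lays out per-locus, per-library
#' expected expression. Known genes selected for differential expression get
#' `de_fold`-fold higher expression in one library (alternating direction).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character, `chr1`), `truth` (one row per
#'   small-RNA-emitting unit), `expression` (unit x library expected means),
#'   `mature_reference` (one row per precursor locus: `mature_name`,
#'   `precursor_id`, `family_key`, `sequence`), `contaminants`, `ncrna_db`,
#'   `family_map`, `annotation` (GRanges, GFF3-ready).
#' @export
build_simulation <- function(config) {
  with_seed(config$seed, build_simulation_impl(config))
}

build_simulation_impl <- function(cfg) {
  genome <- random_dna(cfg$genome_length)
  n_dup <- floor(cfg$n_known_mirnas * cfg$family_duplicate_fraction)
  n_known_loci <- cfg$n_known_mirnas + n_dup
  n_slots <- n_known_loci + cfg$n_novel_hairpins + cfg$n_contaminant_loci +
    cfg$n_decoy_loci
  spacing <- if (n_slots > 0) (cfg$genome_length - 400L) %/% max(n_slots, 1L) else 0L
  slot_pos <- 200L + (seq_len(max(n_slots, 0L)) - 1L) * spacing
  slot <- 0L
  next_slot <- function() { slot <<- slot + 1L; slot_pos[slot] }

  truth <- list(); expr <- list(); mref <- list(); ann <- list()
  rand_len <- function(r) sample(seq(r[1], r[2]), 1L)

  # --- known miRNA genes (first n_dup genes have two loci) ---------------
  de_genes <- integer(0)
  dominant_gene <- if (cfg$n_known_mirnas > 0 &&
                       cfg$dominant_locus_factor > 1) {
    cfg$n_known_mirnas  # single-locus, never DE: the miR-21-like anchor
  } else 0L
  if (cfg$n_known_mirnas > 0) {
    eligible <- setdiff(seq_len(cfg$n_known_mirnas), dominant_gene)
    n_de <- floor(cfg$n_known_mirnas * cfg$de_fraction)
    if (n_de > 0 && length(eligible) >= n_de) {
      de_genes <- sample(eligible, n_de)
    }
  }
  for (g in seq_len(cfg$n_known_mirnas)) {
    gene <- sprintf("syn-mir-%d", g)
    mature <- random_dna(rand_len(cfg$mature_length_range))
    n_loci <- if (g <= n_dup) 2L else 1L
    for (cp in seq_len(n_loci)) {
      prec_id <- if (n_loci == 2L) sprintf("%s-%d", gene, cp) else gene
      pos <- next_slot()
      strand <- sample(c("+", "-"), 1L)
      ph <- plant_hairpin(genome, mature, rand_len(cfg$loop_length_range), pos,
                          strand, cfg$arm_mismatch_rate)
      genome <- ph$genome
      tr <- ph$truth
      unit <- prec_id
      truth[[length(truth) + 1L]] <- data.frame(
        unit_id = unit, locus_id = prec_id, class = "known_mirna",
        label = gene, arm = "5p", chrom = "chr1",
        start = tr$mature_start, end = tr$mature_end, strand = strand,
        mature_seq = mature,
        precursor_start = tr$precursor_start, precursor_end = tr$precursor_end,
        stringsAsFactors = FALSE)
      mref[[length(mref) + 1L]] <- data.frame(
        mature_name = gene, precursor_id = prec_id, family_key = gene,
        sequence = mature, stringsAsFactors = FALSE)
      ann[[length(ann) + 1L]] <- data.frame(
        type = c("miRNA_primary_transcript", "miRNA"),
        start = c(tr$precursor_start, tr$mature_start),
        end = c(tr$precursor_end, tr$mature_end),
        strand = strand, ID = c(prec_id, paste0(prec_id, "_mature")),
        stringsAsFactors = FALSE)
      # expression: direction alternates among DE genes
      for (li in seq_along(cfg$libraries)) {
        mean_i <- cfg$expression_mean_per_locus
        if (g == dominant_gene) mean_i <- mean_i * cfg$dominant_locus_factor
        if (g %in% de_genes && length(cfg$libraries) >= 2) {
          up_in_b <- (match(g, de_genes) %% 2L) == 0L
          if (li == 2L && up_in_b) mean_i <- mean_i * cfg$de_fold
          if (li == 2L && !up_in_b) mean_i <- mean_i / cfg$de_fold
        }
        expr[[length(expr) + 1L]] <- data.frame(
          unit_id = unit, library_id = cfg$libraries[li], expected_mean = mean_i,
          stringsAsFactors = FALSE)
      }
    }
  }

  # --- novel two-arm hairpins -------------------------------------------
  for (v in seq_len(cfg$n_novel_hairpins)) {
    pos <- next_slot()
    strand <- sample(c("+", "-"), 1L)
    mature <- random_dna(rand_len(cfg$mature_length_range))
    ph <- plant_hairpin(genome, mature, rand_len(cfg$loop_length_range), pos,
                        strand, cfg$arm_mismatch_rate)
    genome <- ph$genome
    tr <- ph$truth
    base <- sprintf("syn-novel-%d", v)
    for (arm in c("5p", "3p")) {
      unit <- paste0(base, "-", arm)
      if (arm == "5p") {
        iv <- c(tr$mature_start, tr$mature_end); rs <- mature
      } else {
        iv <- c(tr$star_start, tr$star_end); rs <- tr$star_seq
      }
      truth[[length(truth) + 1L]] <- data.frame(
        unit_id = unit, locus_id = base, class = "novel_hairpin",
        label = unit, arm = arm, chrom = "chr1",
        start = iv[1], end = iv[2], strand = strand, mature_seq = rs,
        precursor_start = tr$precursor_start, precursor_end = tr$precursor_end,
        stringsAsFactors = FALSE)
      for (lib in cfg$libraries) {
        expr[[length(expr) + 1L]] <- data.frame(
          unit_id = unit, library_id = lib,
          expected_mean = cfg$expression_mean_per_locus,
          stringsAsFactors = FALSE)
      }
    }
    # wrap the second novel hairpin in a host gene so its context is
    # intronic; exons sit beyond the +/-100 nt extension reach
    if (v == 2L) {
      gs <- tr$precursor_start - 250L; ge <- tr$precursor_end + 250L
      ann[[length(ann) + 1L]] <- data.frame(
        type = c("gene", "exon", "exon"),
        start = c(gs, gs, ge - 29L), end = c(ge, gs + 29L, ge),
        strand = strand,
        ID = paste0("host_gene_", v, c("", "_ex1", "_ex2")),
        stringsAsFactors = FALSE)
    }
  }

  # --- contaminant loci --------------------------------------------------
  cont_classes <- c("rRNA", "tRNA", "repeat", "adapter")
  contaminants <- list()
  for (ci in seq_len(cfg$n_contaminant_loci)) {
    pos <- next_slot()
    cls <- cont_classes[((ci - 1L) %% 4L) + 1L]
    clen <- 60L + 5L * ((ci - 1L) %% 4L)
    cseq <- random_dna(clen)
    substr(genome, pos, pos + clen - 1L) <- cseq
    cname <- sprintf("syn-%s-%d", tolower(cls), ci)
    contaminants[[ci]] <- data.frame(name = cname, class = cls, sequence = cseq,
                                     stringsAsFactors = FALSE)
    read_off <- 15L
    rlen <- 22L
    unit <- cname
    truth[[length(truth) + 1L]] <- data.frame(
      unit_id = unit, locus_id = cname, class = "contaminant", label = cname,
      arm = NA_character_, chrom = "chr1",
      start = pos + read_off, end = pos + read_off + rlen - 1L, strand = "+",
      mature_seq = substr(cseq, read_off + 1L, read_off + rlen),
      precursor_start = pos, precursor_end = pos + clen - 1L,
      stringsAsFactors = FALSE)
    for (lib in cfg$libraries) {
      expr[[length(expr) + 1L]] <- data.frame(
        unit_id = unit, library_id = lib,
        expected_mean = cfg$expression_mean_per_locus,
        stringsAsFactors = FALSE)
    }
  }

  # --- decoy loci (no structure planted; reads from raw genome) ----------
  for (d in seq_len(cfg$n_decoy_loci)) {
    pos <- next_slot()
    rlen <- 22L
    unit <- sprintf("syn-decoy-%d", d)
    truth[[length(truth) + 1L]] <- data.frame(
      unit_id = unit, locus_id = unit, class = "decoy", label = unit,
      arm = NA_character_, chrom = "chr1",
      start = pos, end = pos + rlen - 1L, strand = "+",
      mature_seq = substr(genome, pos, pos + rlen - 1L),
      precursor_start = pos, precursor_end = pos + rlen - 1L,
      stringsAsFactors = FALSE)
    for (lib in cfg$libraries) {
      expr[[length(expr) + 1L]] <- data.frame(
        unit_id = unit, library_id = lib,
        expected_mean = cfg$expression_mean_per_locus,
        stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, truth)
  expr <- do.call(rbind, expr)
  mature_reference <- if (length(mref)) do.call(rbind, mref) else
    data.frame(mature_name = character(0), precursor_id = character(0),
               family_key = character(0), sequence = character(0))

  # curated ncRNA database: known matures, contaminant-derived records, a few
  # decoy snoRNAs, and an "unclassified RNA" record containing the first
  # novel 5' arm (a smiRNAdb-style subject)
  db <- list()
  for (k in seq_len(nrow(mature_reference))) {
    db[[length(db) + 1L]] <- data.frame(
      name = mature_reference$precursor_id[k], type = "miRNA",
      sequence = mature_reference$sequence[k], stringsAsFactors = FALSE)
  }
  cont_df <- if (length(contaminants)) do.call(rbind, contaminants) else NULL
  if (!is.null(cont_df)) {
    for (k in which(cont_df$class %in% c("rRNA", "tRNA"))) {
      db[[length(db) + 1L]] <- data.frame(
        name = cont_df$name[k], type = cont_df$class[k],
        sequence = cont_df$sequence[k], stringsAsFactors = FALSE)
    }
  }
  for (s in 1:2) {
    db[[length(db) + 1L]] <- data.frame(
      name = sprintf("syn-snorna-%d", s), type = "snoRNA",
      sequence = random_dna(70L), stringsAsFactors = FALSE)
  }
  nov5 <- truth[truth$class == "novel_hairpin" & truth$arm == "5p", ]
  if (nrow(nov5) >= 1) {
    db[[length(db) + 1L]] <- data.frame(
      name = "syn-smlrna-1", type = "unclassified RNA",
      sequence = paste0(substr(nov5$mature_seq[1], 1, nchar(nov5$mature_seq[1])),
                        random_dna(4L)),
      stringsAsFactors = FALSE)
  }
  ncrna_db <- do.call(rbind, db)

  ann_df <- if (length(ann)) do.call(rbind, ann) else NULL
  annotation <- if (!is.null(ann_df)) {
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(ann_df$start, ann_df$end),
                           strand = ann_df$strand,
                           type = ann_df$type, ID = ann_df$ID)
  } else GenomicRanges::GRanges()

  family_map <- mature_reference[, c("mature_name", "precursor_id", "family_key")]

  list(genome = c(chr1 = genome), truth = truth, expression = expr,
       mature_reference = mature_reference,
       contaminants = cont_df %||% data.frame(name = character(0),
                                              class = character(0),
                                              sequence = character(0)),
       ncrna_db = ncrna_db, family_map = family_map, annotation = annotation,
       config = cfg)
}

#' Simulate reads from a truth table
#'
#' Per-unit, per-library counts are Poisson around the expected mean (or
#' exactly the mean with `fixed_counts`); each read is the unit's mature
#' sequence with uniform 0..`read_end_jitter` nt trimmed from each end and
#' per-base substitution errors at `error_rate`.
#'
#' @param sim output of [build_simulation()] (or a list with `truth`,
#'   `expression`, `config`).
#' @param config optional [sim_config()] override.
#' @return list: `reads` (collapsed read records, see [collapse_reads()]),
#'   `fastq` (data.frame `id`, `sequence`, `library_id` - one row per read
#'   copy), `read_truth` (read id -> unit id), `draws` (unit x library drawn
#'   counts).
#' @export
simulate_reads <- function(sim, config = NULL) {
  cfg <- config %||% sim$config
  truth <- sim$truth
  if (is.null(truth) || nrow(truth) == 0) stopf("truth table is empty")
  with_seed(cfg$seed + 1L, {
    expr <- sim$expression
    chunks <- vector("list", nrow(expr))
    draws <- expr
    draws$count <- 0L
    for (k in seq_len(nrow(expr))) {
      unit <- expr$unit_id[k]; lib <- expr$library_id[k]
      n <- draw_count(expr$expected_mean[k], cfg$fixed_counts)
      draws$count[k] <- n
      if (n == 0L) next
      base_seq <- truth$mature_seq[match(unit, truth$unit_id)]
      s <- rep(base_seq, n)
      if (cfg$read_end_jitter > 0) {
        t5 <- sample(0:cfg$read_end_jitter, n, replace = TRUE)
        t3 <- sample(0:cfg$read_end_jitter, n, replace = TRUE)
        keep <- nchar(s) - t5 - t3 >= 15L
        s[keep] <- substr(s[keep], 1L + t5[keep], nchar(s[keep]) - t3[keep])
      }
      if (cfg$error_rate > 0) {
        s <- vapply(s, mutate_sequence, "", rate = cfg$error_rate,
                    USE.NAMES = FALSE)
      }
      chunks[[k]] <- data.frame(
        id = sprintf("%s|%s|%d library=%s", lib, unit, seq_len(n), lib),
        sequence = s, library_id = lib, unit_id = unit,
        stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
    fastq <- all[, c("id", "sequence", "library_id")]
    read_truth <- all[, c("id", "unit_id", "library_id")]
    list(reads = collapse_reads(all$sequence, all$library_id),
         fastq = fastq, read_truth = read_truth, draws = draws)
  })
}

#' Write a complete fixture bundle to disk
#'
#' Emits genome FASTA, mature reference FASTA, annotation GFF3, family map
#' TSV, contaminant FASTA, ncRNA database FASTA (with `type=` header keys),
#' reads FASTQ (constant quality, library in the header) and the truth TSV,
#' plus a JSON manifest with per-file MD5 checksums. Regeneration under the
#' same seed is byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisible list: `manifest` path, `files` named paths, `sim`,
#'   `reads` (the in-memory objects).
#' @export
make_fixture <- function(config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stopf("cannot create directory: %s", out_dir)
  }
  sim <- build_simulation(config)
  rd <- simulate_reads(sim)
  fp <- function(x) file.path(out_dir, x)
  files <- c(genome = fp("genome.fa"), mature = fp("mature_ref.fa"),
             annotation = fp("annotation.gff3"), family_map = fp("family_map.tsv"),
             contaminants = fp("contaminants.fa"), ncrna_db = fp("ncrna_db.fa"),
             reads = fp("reads.fastq"), truth = fp("truth.tsv"))
  write_fasta("chr1", unname(sim$genome["chr1"]), files["genome"])
  mr <- sim$mature_reference
  mu <- mr[!duplicated(mr$mature_name), ]
  write_fasta(sprintf("%s family=%s", mu$mature_name, mu$family_key),
              mu$sequence, files["mature"])
  write_annotation(sim$annotation, files["annotation"])
  write_tsv(sim$family_map, files["family_map"])
  write_fasta(sprintf("%s class=%s", sim$contaminants$name,
                      sim$contaminants$class),
              sim$contaminants$sequence, files["contaminants"])
  write_fasta(sprintf("%s type=%s", sim$ncrna_db$name, sim$ncrna_db$type),
              sim$ncrna_db$sequence, files["ncrna_db"])
  write_fastq(rd$fastq$id, rd$fastq$sequence, files["reads"])
  write_tsv(sim$truth, files["truth"])
  sums <- tools::md5sum(unname(files))
  manifest <- list(
    files = lapply(seq_along(files), function(k) {
      list(role = names(files)[k], path = basename(files[k]),
           md5 = unname(sums[k]))
    }),
    seed = config$seed
  )
  manifest_path <- fp("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest_path, files = files, sim = sim, reads = rd))
}
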