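# Pipeline orchestration: configuration with the published default
# thresholds, the quantification branch (filter -> match -> assign -> count
# -> normalize -> DE/unique/top/common), the discovery branch (select -> map
# -> cluster -> extend -> fold -> classify -> similarity -> exclude -> merge
# -> integrate) and report writing.

#' Pipeline configuration
#'
#' Houses every numeric threshold with the documented defaults: mismatch
#' budget 2 with 2 nt terminal shift, 5-hit multi-alignment cap, 2-fold DE
#' rule, 10-read unique-expression cutoff, discovery filter (< 35 nt, >= 10
#' copies), +/-100 nt precursor extension, 10 nt cluster gap, similarity
#' cutoffs 80/80 with word size 6 and e-value 1e-4, structural-search bit
#' score cutoff 25 and ab-initio cutoff 0.71.
#'
#' @param ... overrides for any default, plus optional file paths (`reads`,
#'   `genome`, `mature`, `family_map`, `contaminants`, `ncrna_db`,
#'   `annotation`, `infernal_file`, `hhmmir_file`, `trna_file`, `out_dir`).
#' @param file optional YAML file of key-value overrides (CLI-style); direct
#'   arguments win over the file.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    max_mismatch = 2, max_shift = 2, max_hits = 5, cap_on = "precursors",
    contaminant_max_mismatch = 0,
    scale = 1.0, min_fold = 2.0, min_unique_count = 10,
    min_copies = 10, strict_copies = FALSE, max_len = 35,
    max_loci = 5, max_gap = 10, flank = 100,
    max_separation = 50, min_duplex_pairs = 5,
    word_size = 6, min_identity = 80, min_coverage = 80, max_evalue = 1e-4,
    infernal_cutoff = 25, abinitio_cutoff = 0.71,
    min_loop = 3, bulge_tol = 2,
    reads = NULL, genome = NULL, mature = NULL, family_map = NULL,
    contaminants = NULL, ncrna_db = NULL, annotation = NULL,
    infernal_file = NULL, hhmmir_file = NULL, trna_file = NULL,
    out_dir = NULL, seed = 1L
  )
  overrides <- list(...)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    for (k in names(from_file)) {
      if (!k %in% names(overrides)) overrides[[k]] <- from_file[[k]]
    }
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stopf("unknown config keys: %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

check_input_file <- function(path, what) {
  if (is.null(path)) stopf("config is missing the `%s` input path", what)
  if (!file.exists(path)) stopf("%s file does not exist: %s", what, path)
  path
}

#' Run the quantification branch
#'
#' Per library: contaminant filtering, mature matching, family-aware
#' assignment and counting; then max-normalization, the 2-fold DE call
#' between the first two libraries, uniquely expressed molecules, top-10
#' representation and the common-miRNA percentage.
#'
#' @param config a [pipeline_config()] with input paths, or with `inputs`
#'   supplied in-memory.
#' @param inputs optional list with `reads` (read records for all
#'   libraries), `reference` (mature reference table), `contaminants`;
#'   bypasses file loading (e.g. straight from [make_fixture()]).
#' @return a `quantify_result`: `profiles` (named list of normalized
#'   [quantify()] profiles), `de` table, `unique`, `top` (per library),
#'   `comparison` (per-library detected/common/percentage), `ledger`
#'   (per-library copy accounting).
#' @export
run_quantify <- function(config = pipeline_config(), inputs = NULL) {
  if (is.null(inputs)) {
    reads <- read_reads(check_input_file(config$reads, "reads"))
    mature <- read_fasta(check_input_file(config$mature, "mature"))
    fam <- if (!is.null(config$family_map)) {
      read_family_map(check_input_file(config$family_map, "family_map"))
    } else NULL
    reference <- build_mature_reference(mature, fam)
    contaminants <- if (!is.null(config$contaminants)) {
      fa <- read_fasta(check_input_file(config$contaminants, "contaminants"))
      data.frame(name = fa$name,
                 class = sub(".*class=([^ ]+).*", "\\1", fa$desc),
                 sequence = fa$sequence, stringsAsFactors = FALSE)
    } else NULL
  } else {
    reads <- inputs$reads
    reference <- inputs$reference
    contaminants <- inputs$contaminants
  }
  libs <- sort(unique(reads$library_id))
  profiles <- list()
  ledgers <- list()
  for (lib in libs) {
    p <- quantify(reads[reads$library_id == lib, , drop = FALSE], reference,
                  contaminant_db = contaminants, library_id = lib,
                  max_mismatch = config$max_mismatch,
                  max_shift = config$max_shift, max_hits = config$max_hits,
                  cap_on = config$cap_on)
    p <- normalize_max(p, scale = config$scale)
    profiles[[lib]] <- p
    ledgers[[lib]] <- data.frame(library_id = lib, t(p$ledger))
  }
  de <- NULL; uniq <- NULL; comparison <- NULL
  if (length(libs) >= 2) {
    a <- profiles[[libs[1]]]; b <- profiles[[libs[2]]]
    de <- call_differential(a, b, min_fold = config$min_fold)
    uniq <- unique_expressed(a, b, min_count = config$min_unique_count)
    det_a <- a$entries$label[a$entries$raw_count >= 1]
    det_b <- b$entries$label[b$entries$raw_count >= 1]
    comparison <- data.frame(
      library_id = c(libs[1], libs[2]),
      total_mirnas = c(length(det_a), length(det_b)),
      common_mirnas = length(intersect(det_a, det_b)),
      pct_common = c(common_mirna_percentage(det_a, det_b),
                     common_mirna_percentage(det_b, det_a)))
  }
  top <- lapply(profiles, top_expressed, n = 10)
  structure(list(profiles = profiles, de = de, unique = uniq, top = top,
                 comparison = comparison,
                 ledger = do.call(rbind, ledgers), config = config),
            class = "quantify_result")
}

#' Run the discovery branch
#'
#' From reads matching no known miRNA: abundance/length selection, exact
#' genome mapping, positional clustering, +/-`flank` extension, genomic
#' context, folding, similarity search, false-positive exclusion, merging of
#' adjacent two-arm candidates and evidence integration.
#'
#' @param config a [pipeline_config()].
#' @param quantify_result output of [run_quantify()] (provides the unmatched
#'   reads).
#' @param inputs optional in-memory list with `genome` (named character),
#'   `ncrna_db`, `annotation`; file paths in `config` are used otherwise.
#' @return a `discover_result`: `candidates` (kept, merged), `records`
#'   (evidence records), `table` (report data.frame), `excluded`, `dropped`
#'   (unmappable/multimapped log), `selected` (discovery read set).
#' @export
run_discover <- function(config, quantify_result, inputs = NULL) {
  if (is.null(inputs)) {
    gfa <- read_fasta(check_input_file(config$genome, "genome"))
    genome <- stats::setNames(gfa$sequence, gfa$name)
    dbfa <- if (!is.null(config$ncrna_db)) {
      fa <- read_fasta(check_input_file(config$ncrna_db, "ncrna_db"))
      data.frame(name = fa$name,
                 type = sub(".*type=(.+?)\\s*$", "\\1", fa$desc),
                 sequence = fa$sequence, stringsAsFactors = FALSE)
    } else NULL
    annotation <- if (!is.null(config$annotation)) {
      read_annotation(check_input_file(config$annotation, "annotation"))
    } else NULL
  } else {
    genome <- inputs$genome
    dbfa <- inputs$ncrna_db
    annotation <- inputs$annotation
  }
  trna_calls <- if (!is.null(config$trna_file)) {
    utils::read.table(config$trna_file, stringsAsFactors = FALSE)[[1]]
  } else character(0)
  fam_hits_all <- if (!is.null(config$infernal_file)) {
    parse_infernal_tblout(config$infernal_file, cutoff = config$infernal_cutoff)
  } else NULL
  ext_ab <- if (!is.null(config$hhmmir_file)) {
    read_hhmmir_scores(config$hhmmir_file, cutoff = config$abinitio_cutoff)
  } else NULL

  # unmatched reads pooled over libraries (copy threshold is library-wide),
  # keeping per-library counts for the report
  unmatched <- do.call(rbind, lapply(quantify_result$profiles,
                                     function(p) p$unmatched))
  if (is.null(unmatched) || nrow(unmatched) == 0) {
    pooled <- data.frame(id = character(0), sequence = character(0),
                         count = integer(0), library_id = character(0))
  } else {
    agg <- stats::aggregate(count ~ sequence, data = unmatched, FUN = sum)
    pooled <- data.frame(id = sprintf("pooled_r%05d", seq_len(nrow(agg))),
                         sequence = agg$sequence, count = agg$count,
                         library_id = "pooled", stringsAsFactors = FALSE)
  }
  selected <- select_discovery_reads(pooled, min_copies = config$min_copies,
                                     max_len = config$max_len,
                                     strict_copies = config$strict_copies)
  mp <- map_reads_exact(selected, genome, max_loci = config$max_loci)
  clustered <- cluster_by_position(mp$mapped, max_gap = config$max_gap)
  candidates <- list()
  for (cid in unique(clustered$cluster_id)) {
    cl <- clustered[clustered$cluster_id == cid, , drop = FALSE]
    candidates[[length(candidates) + 1L]] <-
      extend_cluster(cl, genome, flank = config$flank,
                     candidate_id = sprintf("cand%02d", length(candidates) + 1L))
  }
  candidates <- assign_genomic_context(candidates, annotation)

  sim_hits <- if (!is.null(dbfa) && length(candidates) > 0) {
    do.call(rbind, lapply(candidates, similarity_search, ncrna_db = dbfa,
                          word_size = config$word_size,
                          min_identity = config$min_identity,
                          min_coverage = config$min_coverage,
                          max_evalue = config$max_evalue))
  } else NULL

  ex <- exclude_false_positives(candidates, annotation = annotation,
                                similarity_hits = sim_hits,
                                trna_calls = trna_calls)
  kept <- merge_adjacent_candidates(ex$kept, genome,
                                    max_separation = config$max_separation,
                                    min_duplex_pairs = config$min_duplex_pairs)
  kept <- dedup_mirror_candidates(kept)

  # per-library normalized counts for reporting: raw candidate read counts
  # scaled by each library's miRNA-profile maximum
  lib_max <- vapply(quantify_result$profiles, function(p)
    max(p$entries$raw_count, 1), 1)
  per_lib_counts <- function(cand) {
    seqs <- cand$reads$sequence
    out <- numeric(0)
    for (lib in names(quantify_result$profiles)) {
      um <- quantify_result$profiles[[lib]]$unmatched
      raw <- sum(um$count[um$sequence %in% seqs])
      out[lib] <- raw / lib_max[[lib]] * config$scale
    }
    out
  }

  records <- list()
  for (cand in kept) {
    st <- fold_nussinov(cand$precursor_sequence, min_loop = config$min_loop)
    ids <- c(cand$candidate_id, cand$merged_from)
    sh <- if (!is.null(sim_hits)) {
      sim_hits[sim_hits$candidate_id %in% ids, , drop = FALSE]
    } else NULL
    fh <- if (!is.null(fam_hits_all)) {
      fam_hits_all[fam_hits_all$candidate_id %in% ids, , drop = FALSE]
    } else NULL
    ab <- if (!is.null(ext_ab) && any(ext_ab$candidate_id %in% ids)) {
      max(ext_ab$score[ext_ab$candidate_id %in% ids])
    } else {
      rd <- cand$reads[which.max(cand$reads$count), ]
      score_abinitio(hairpin_features(st, rd$prec_start, rd$prec_end,
                                      bulge_tol = config$bulge_tol))
    }
    rec <- integrate_evidence(
      cand, st, similarity_hits = sh, family_hits = fh, abinitio_score = ab,
      norm_counts = per_lib_counts(cand),
      abinitio_cutoff = config$abinitio_cutoff)
    rec$mature_proposals <- propose_mature(cand, st)
    records[[length(records) + 1L]] <- rec
  }
  # excluded candidates still get a row, with their reason
  for (k in seq_len(nrow(ex$excluded))) {
    cand <- candidates[[match(ex$excluded$candidate_id[k],
                              vapply(candidates, `[[`, "", "candidate_id"))]]
    st <- fold_nussinov(cand$precursor_sequence, min_loop = config$min_loop)
    records[[length(records) + 1L]] <- integrate_evidence(
      cand, st, similarity_hits = NULL, family_hits = NULL,
      abinitio_score = NA, excluded_reason = ex$excluded$reason[k],
      norm_counts = per_lib_counts(cand),
      abinitio_cutoff = config$abinitio_cutoff)
  }
  tab <- if (length(records)) evidence_table(records) else NULL
  structure(list(candidates = kept, all_candidates = candidates,
                 records = records, table = tab,
                 excluded = ex$excluded, dropped = mp$dropped,
                 selected = selected, config = config),
            class = "discover_result")
}

#' Write all pipeline reports
#'
#' TSVs (per-library counts and normalized values, DE, unique sets, top-N,
#' comparison, candidate evidence, ledger), BED6 and GFF3 candidate exports,
#' precursor FASTA (read offsets in the description) and a JSON run manifest
#' with the configuration hash and package version.
#'
#' @param quantify_result from [run_quantify()].
#' @param discover_result from [run_discover()] (optional).
#' @param out_dir output directory.
#' @return invisible named vector of written paths.
#' @export
write_reports <- function(quantify_result, discover_result = NULL, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  paths <- c()
  counts <- do.call(rbind, lapply(quantify_result$profiles, function(p)
    cbind(library_id = p$library_id, p$entries)))
  write_tsv(counts, fp("counts.tsv")); paths["counts"] <- fp("counts.tsv")
  write_tsv(quantify_result$ledger, fp("ledger.tsv"))
  paths["ledger"] <- fp("ledger.tsv")
  if (!is.null(quantify_result$de)) {
    write_tsv(quantify_result$de, fp("differential.tsv"))
    paths["differential"] <- fp("differential.tsv")
  }
  if (!is.null(quantify_result$unique)) {
    uq <- quantify_result$unique
    uqd <- rbind(
      if (length(uq$unique_a)) data.frame(side = "A", label = uq$unique_a),
      if (length(uq$unique_b)) data.frame(side = "B", label = uq$unique_b))
    if (is.null(uqd)) uqd <- data.frame(side = character(0), label = character(0))
    write_tsv(uqd, fp("unique_expressed.tsv"))
    paths["unique"] <- fp("unique_expressed.tsv")
  }
  topd <- do.call(rbind, lapply(names(quantify_result$top), function(lib)
    cbind(library_id = lib, quantify_result$top[[lib]])))
  write_tsv(topd, fp("top_expressed.tsv"))
  paths["top"] <- fp("top_expressed.tsv")
  if (!is.null(quantify_result$comparison)) {
    write_tsv(quantify_result$comparison, fp("comparison.tsv"))
    paths["comparison"] <- fp("comparison.tsv")
  }
  if (!is.null(discover_result)) {
    if (!is.null(discover_result$table)) {
      write_tsv(discover_result$table, fp("candidates.tsv"))
      paths["candidates"] <- fp("candidates.tsv")
    }
    gr <- candidates_to_granges(discover_result$candidates)
    if (length(gr) > 0) {
      rtracklayer::export(gr, fp("candidates.bed"), format = "bed")
      mcols(gr)$type <- "miRNA_candidate"
      mcols(gr)$ID <- mcols(gr)$name
      write_annotation(gr, fp("candidates.gff3"))
      paths["bed"] <- fp("candidates.bed")
      paths["gff3"] <- fp("candidates.gff3")
      hdr <- vapply(discover_result$candidates, function(x)
        sprintf("%s %s:%d-%d(%s) offsets=%s", x$candidate_id, x$chrom,
                x$start, x$end, x$strand,
                paste(x$reads$offset, collapse = ",")), "")
      write_fasta(hdr, vapply(discover_result$candidates, `[[`, "",
                              "precursor_sequence"),
                  fp("precursors.fa"))
      paths["precursors"] <- fp("precursors.fa")
    }
  }
  cfg <- quantify_result$config
  cfg_file <- fp("config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], cfg_file)
  paths["config"] <- cfg_file
  manifest <- list(tool = "srnamine",
                   version = as.character(utils::packageVersion("srnamine")),
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   outputs = as.list(stats::setNames(basename(paths),
                                                     names(paths))))
  jsonlite::write_json(manifest, fp("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  paths["manifest"] <- fp("run_manifest.json")
  invisible(paths)
}
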