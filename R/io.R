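# File input/output: FASTA/FASTQ, TSV tables, GFF3, Vienna structure files.
# Reading goes through Biostrings/rtracklayer; writing uses fixed layouts so
# that regenerated fixture bundles are byte-identical for a fixed seed.

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return data.frame with columns `name` (first header token), `desc` (full
#'   header line) and `sequence` (upper-case DNA).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  data.frame(
    name = vapply(strsplit(desc, "\\s+"), `[`, "", 1L),
    desc = desc,
    sequence = toupper(as.character(x)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write sequences as FASTA
#'
#' @param names,sequences parallel character vectors; `names` are full header
#'   lines (without the leading `>`).
#' @param path output path.
#' @export
write_fasta <- function(names, sequences, path) {
  stopifnot(length(names) == length(sequences))
  con <- file(path, "wb")  # binary: fixed "\n" endings for determinism
  on.exit(close(con))
  writeLines(paste0(">", names, "\n", sequences), con, sep = "\n")
  invisible(path)
}

#' Read small-RNA reads from FASTQ or FASTA
#'
#' Identical sequences are collapsed per library and copy counts carried
#' (never recomputed downstream). FASTA headers may carry pre-collapsed counts
#' as a `_x<count>` suffix; library of origin is read from a `library=<id>`
#' key in the description, falling back to `library_id`.
#'
#' @param path FASTQ/FASTA file.
#' @param format `"fastq"` or `"fasta"`.
#' @param library_id fallback library label.
#' @return data.frame of read records: `id`, `sequence`, `count`, `library_id`.
#' @export
read_reads <- function(path, format = c("fastq", "fasta"), library_id = "lib1") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("reads file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = format)
  desc <- names(x)
  lib <- ifelse(grepl("library=", desc),
                sub(".*library=([^ ]+).*", "\\1", desc), library_id)
  count <- ifelse(grepl("_x(\\d+)", desc),
                  as.integer(sub(".*_x(\\d+).*", "\\1", desc)), 1L)
  collapse_reads(toupper(as.character(x)), lib, count)
}

#' Collapse identical read sequences per library
#'
#' @param sequences character vector of read sequences.
#' @param library_id character vector (recycled) of library labels.
#' @param count per-entry copy counts (default 1).
#' @return data.frame of unique (library, sequence) records with summed counts.
#' @export
collapse_reads <- function(sequences, library_id = "lib1", count = 1L) {
  d <- data.frame(sequence = sequences, library_id = library_id,
                  count = as.integer(count), stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ library_id + sequence, data = d, FUN = sum)
  agg <- agg[order(agg$library_id, agg$sequence), , drop = FALSE]
  agg$id <- sprintf("%s_r%05d_x%d", agg$library_id, seq_len(nrow(agg)), agg$count)
  rownames(agg) <- NULL
  agg[, c("id", "sequence", "count", "library_id")]
}

write_fastq <- function(ids, sequences, path, quality_char = "I") {
  con <- file(path, "wb")
  on.exit(close(con))
  qual <- vapply(nchar(sequences), function(n)
    paste(rep(quality_char, n), collapse = ""), "")
  writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a miRNA family map
#'
#' Three tab-separated columns: `mature_name`, `precursor_id`, `family_key`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_family_map <- function(path) {
  fm <- read_tsv(path)
  need <- c("mature_name", "precursor_id", "family_key")
  if (!all(need %in% names(fm))) {
    stopf("family map %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  fm
}

#' Derive a family key from a precursor name
#'
#' Strips a trailing `-<digits>` locus-copy suffix, so `hsa-mir-103a-1` and
#' `hsa-mir-103a-2` both map to family `hsa-mir-103a`. An explicit family map
#' file overrides this rule wherever one is supplied.
#'
#' @param precursor_id character vector of precursor names.
#' @return character vector of family keys.
#' @export
family_key_from_name <- function(precursor_id) {
  sub("-\\d+$", "", precursor_id)
}

# --- GFF3 via rtracklayer -----------------------------------------------

#' Import annotation features from GFF3
#'
#' @param path GFF3 file (1-based inclusive coordinates, as standard).
#' @return a [GenomicRanges::GRanges] with a `type` column.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  rtracklayer::import(path, format = "gff3")
}

#' Export candidate loci as GFF3
#'
#' @param gr a GRanges object with `ID`s in `mcols`.
#' @param path output path.
#' @export
write_annotation <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# --- Vienna-style structure files ---------------------------------------

#' Read a Vienna-style structure file
#'
#' Records of: a `>` header line, a sequence line, and a dot-bracket line with
#' an optional trailing `(energy)` in kcal/mol, the layout RNAfold prints.
#'
#' @param path file path.
#' @return list of [secondary_structure()] objects (energy kept when present).
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stopf("no '>' records in %s", path)
  out <- vector("list", length(heads))
  ends <- c(heads[-1] - 1L, length(lines))
  for (k in seq_along(heads)) {
    block <- lines[(heads[k] + 1L):ends[k]]
    if (length(block) < 2L) stopf("record %d in %s lacks structure line", k, path)
    seq <- block[1]
    sline <- block[2]
    energy <- NA_real_
    m <- regmatches(sline, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sline))
    if (length(m) == 1L && nzchar(m)) {
      energy <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
      sline <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", sline)
    }
    st <- parse_dotbracket(seq, trimws(sline))
    if (!is.na(energy)) st$energy_score <- energy
    st$name <- sub("^>\\s*", "", lines[heads[k]])
    out[[k]] <- st
  }
  out
}

#' @rdname read_vienna
#' @param structures list of secondary structures.
#' @export
write_vienna <- function(structures, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (st in structures) {
    writeLines(c(paste0(">", st$name %||% "structure"),
                 st$sequence,
                 sprintf("%s (%.2f)", st$dot_bracket, st$energy_score)),
               con, sep = "\n")
  }
  invisible(path)
}
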