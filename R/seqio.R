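#' Read a dataset of MTS / mature sequence pairs
#'
#' Canonical input is a TSV with columns `record_id`, `species`,
#' `gene_id`, `accession`, `mts_seq`, `mature_seq` (`.` for missing
#' optional fields). Alternatively, `format = "fasta_pair"` reads one
#' FASTA file of full precursors whose description lines carry
#' `cleavage=<k>` (1-based index of the last MTS residue) and optionally
#' `species=<tag>`; each precursor is split at the cleavage site.
#'
#' Sequences are uppercased on load. Records violating the invariants
#' (empty part, residue outside the standard alphabet plus X,B,Z,U,O,J,
#' or more than `maxUnknownFrac` unknown residues in either part) are
#' rejected with a per-record reason, available via [rejectedRecords()];
#' a warning summarizes the rejections. File order is preserved.
#'
#' @param path input file.
#' @param format `"tsv"` (default) or `"fasta_pair"`.
#' @param speciesLevels optional configured species set; records with
#'   other tags are rejected. `NULL` accepts all observed tags.
#' @param maxUnknownFrac maximum tolerated fraction of unknown residues
#'   per part (default 0.05).
#' @return A validated [MtsDataset-class] (with `rejected` records noted).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeDataset(MtsDataset("r1", "Hsap", "MAAARSTK", "MKLVNAAD"), tf)
#' readDataset(tf)
#' @export
readDataset <- function(path, format = c("tsv", "fasta_pair"),
                        speciesLevels = NULL, maxUnknownFrac = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("input file does not exist: %s", path), call. = FALSE)
  raw <- if (format == "tsv") readDatasetTsv(path) else readDatasetFasta(path)
  if (nrow(raw) == 0)
    stop(sprintf("input file has no records: %s", path), call. = FALSE)
  if (anyDuplicated(raw$record_id))
    stop(sprintf("duplicate record_id: %s",
                 paste(unique(raw$record_id[duplicated(raw$record_id)]),
                       collapse = ", ")), call. = FALSE)
  raw$mts_seq <- toupper(raw$mts_seq)
  raw$mature_seq <- toupper(raw$mature_seq)

  reason <- vapply(seq_len(nrow(raw)), function(i) {
    r <- checkAminoSeq(raw$mts_seq[i])
    if (!is.null(r)) return(paste0("mts_seq: ", r))
    r <- checkAminoSeq(raw$mature_seq[i])
    if (!is.null(r)) return(paste0("mature_seq: ", r))
    if (unknownFraction(raw$mts_seq[i]) > maxUnknownFrac ||
        unknownFraction(raw$mature_seq[i]) > maxUnknownFrac)
      return(sprintf("too many unknown residues (> %g%%)",
                     100 * maxUnknownFrac))
    if (!is.null(speciesLevels) && !(raw$species[i] %in% speciesLevels))
      return(sprintf("species '%s' not in configured set", raw$species[i]))
    NA_character_
  }, character(1))

  keep <- is.na(reason)
  rejected <- data.frame(record_id = raw$record_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    warning(sprintf("%d record(s) rejected on load (see rejectedRecords()); first: %s [%s]",
                    nrow(rejected), rejected$record_id[1],
                    rejected$reason[1]), call. = FALSE)
  kept <- raw[keep, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("all records were rejected on load", call. = FALSE)
  ds <- MtsDataset(recordId = kept$record_id, species = kept$species,
                   mts = kept$mts_seq, mature = kept$mature_seq,
                   geneId = kept$gene_id, accession = kept$accession,
                   provenance = path)
  ds@rejected <- rejected
  validObject(ds)
  ds
}

readDatasetTsv <- function(path) {
  required <- c("record_id", "species", "mts_seq", "mature_seq")
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (opt in c("gene_id", "accession"))
    if (!opt %in% names(tab)) tab[[opt]] <- "."
  tab$gene_id[tab$gene_id %in% c(".", "")] <- NA_character_
  tab$accession[tab$accession %in% c(".", "")] <- NA_character_
  tab[, c("record_id", "species", "gene_id", "accession",
          "mts_seq", "mature_seq")]
}

readDatasetFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0)
    return(data.frame(record_id = character(), species = character(),
                      gene_id = character(), accession = character(),
                      mts_seq = character(), mature_seq = character(),
                      stringsAsFactors = FALSE))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  getField <- function(h, key) {
    m <- regmatches(h, regexec(paste0(key, "=([^\\s]+)"), h, perl = TRUE))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  cleav <- suppressWarnings(
    as.integer(vapply(headers, getField, character(1), key = "cleavage")))
  if (anyNA(cleav))
    stop("fasta_pair input: every description line needs 'cleavage=<k>'",
         call. = FALSE)
  spec <- vapply(headers, getField, character(1), key = "species")
  spec[is.na(spec)] <- "unknown"
  full <- as.character(seqs)
  parts <- mapply(function(s, k) splitFullSequence(s, k), full, cleav,
                  SIMPLIFY = FALSE)
  data.frame(record_id = ids, species = unname(spec),
             gene_id = NA_character_, accession = NA_character_,
             mts_seq = vapply(parts, `[[`, character(1), "mts"),
             mature_seq = vapply(parts, `[[`, character(1), "mature"),
             stringsAsFactors = FALSE)
}

#' Write a dataset to the canonical TSV layout
#'
#' Inverse of [readDataset()]: writes `record_id`, `species`, `gene_id`,
#' `accession`, `mts_seq`, `mature_seq`, with `.` for missing optional
#' fields, so that `readDataset(writeDataset(d))` round-trips exactly.
#'
#' @param dataset an [MtsDataset-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeDataset <- function(dataset, path) {
  tab <- as.data.frame(dataset)
  tab$gene_id[is.na(tab$gene_id)] <- "."
  tab$accession[is.na(tab$accession)] <- "."
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a full precursor at its cleavage site
#'
#' @param fullSeq full precursor amino-acid string.
#' @param cleavagePos 1-based index of the last MTS residue; must satisfy
#'   `1 <= cleavagePos < nchar(fullSeq)`.
#' @return list with elements `mts` (residues 1..cleavagePos) and
#'   `mature` (the rest); their concatenation equals `fullSeq`.
#' @examples
#' splitFullSequence("MAAARSTK", 4)
#' @export
splitFullSequence <- function(fullSeq, cleavagePos) {
  stopifnot(is.character(fullSeq), length(fullSeq) == 1L)
  n <- nchar(fullSeq)
  if (!is.numeric(cleavagePos) || length(cleavagePos) != 1L ||
      is.na(cleavagePos) || cleavagePos < 1 || cleavagePos >= n)
    stop(sprintf("cleavagePos must satisfy 1 <= pos < %d", n),
         call. = FALSE)
  cleavagePos <- as.integer(cleavagePos)
  list(mts = substr(fullSeq, 1L, cleavagePos),
       mature = substr(fullSeq, cleavagePos + 1L, n))
}

#' Write a rectangular result table as TSV
#'
#' Writes a data.frame (or matrix, whose row names become a leading
#' `row` column) with a header line; numeric columns are rounded to
#' `digits` significant digits.
#'
#' @param table data.frame or matrix with unique row/column labels.
#' @param path output file.
#' @param digits significant digits for floating values (default 6).
#' @return Invisibly, `path`.
#' @export
writeTable <- function(table, path, digits = 6) {
  if (is.matrix(table)) {
    table <- data.frame(row = rownames(table), table,
                        check.names = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table)))
    stop("column labels must be unique", call. = FALSE)
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write to '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
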