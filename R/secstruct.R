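#' Read per-residue secondary-structure / disorder annotations
#'
#' Annotations are consumed, not predicted: a TSV with columns
#' `record_id`, `ss` (per-residue string over H/E/L) and `disorder`
#' (per-residue mask over D and `.`). When a dataset is supplied, each
#' annotation must match the length of that record's mature sequence and
#' annotations for unknown records are an error. An annotation file with
#' a header but no rows yields an empty collection with a warning (the
#' secondary-structure stage is then skipped).
#'
#' @param path annotation TSV.
#' @param dataset optional [MtsDataset-class] to validate against.
#' @return A [SecStructAnnotations-class].
#' @export
readAnnotations <- function(path, dataset = NULL) {
  if (!file.exists(path))
    stop(sprintf("annotation file does not exist: %s", path), call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  required <- c("record_id", "ss", "disorder")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop(sprintf("annotation file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(tab) == 0) {
    warning("annotation file has no rows; secondary-structure stage will be skipped",
            call. = FALSE)
    return(SecStructAnnotations())
  }
  ann <- SecStructAnnotations(recordId = tab$record_id, ss = tab$ss,
                              disorder = tab$disorder)
  if (!is.null(dataset)) {
    unknown <- setdiff(recordId(ann), recordId(dataset))
    if (length(unknown) > 0)
      stop(sprintf("annotation for unknown record(s): %s",
                   paste(head(unknown, 3), collapse = ", ")), call. = FALSE)
    matLen <- nchar(as.character(matureSeqs(dataset)))
    names(matLen) <- recordId(dataset)
    bad <- recordId(ann)[nchar(ssStrings(ann)) != matLen[recordId(ann)]]
    if (length(bad) > 0)
      stop(sprintf("annotation length differs from mature sequence for: %s",
                   paste(head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  ann
}

#' Write annotations to TSV
#'
#' @param annotations a [SecStructAnnotations-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeAnnotations <- function(annotations, path) {
  tab <- data.frame(record_id = recordId(annotations),
                    ss = unname(ssStrings(annotations)),
                    disorder = unname(disorderStrings(annotations)),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Windowed secondary-structure proportions
#'
#' Fractions of helix (H), strand (E) and disordered (D) residues over an
#' N-terminal window of one annotation. The window is always truncated to
#' the annotation length (Fig-4-style analysis windows); the effective
#' window length is reported as `n`.
#'
#' @param ss per-residue H/E/L string.
#' @param disorder per-residue D/"." mask, same length as `ss`.
#' @param w a [windowSpec()] (its policy is ignored; truncation applies).
#' @return list(`helix`, `strand`, `other`, `disorder`, `n`), or `NULL`
#'   when the window lies entirely beyond the annotation.
#' @examples
#' windowSsProportions(strrep("H", 50), strrep(".", 50), windowSpec(1, 50))
#' @export
windowSsProportions <- function(ss, disorder, w) {
  stopifnot(is.character(ss), length(ss) == 1L,
            nchar(ss) == nchar(disorder), inherits(w, "WindowSpec"))
  n <- nchar(ss)
  if (w$start > n) return(NULL)
  end <- min(w$end, n)
  sub <- strsplit(substr(ss, w$start, end), "", fixed = TRUE)[[1]]
  dsub <- strsplit(substr(disorder, w$start, end), "", fixed = TRUE)[[1]]
  m <- length(sub)
  list(helix = sum(sub == "H") / m,
       strand = sum(sub == "E") / m,
       other = sum(sub == "L") / m,
       disorder = sum(dsub == "D") / m,
       n = m)
}

#' Select the shortest- and longest-MTS record groups of a species
#'
#' Deterministically picks the `k` records with the shortest and the `k`
#' with the longest targeting signals within one species. Ties in MTS
#' length are broken by lexicographic record id, so the selection is a
#' pure function of (dataset, species, k). The two groups are disjoint.
#'
#' @param dataset an [MtsDataset-class].
#' @param speciesTag species to subset.
#' @param k group size; `NULL` picks 10 when the species has at least 80
#'   records and 5 otherwise.
#' @return list(`short`, `long`): two disjoint [MtsDataset-class] objects
#'   of `k` records each.
#' @export
selectExtremeMtsGroups <- function(dataset, speciesTag, k = NULL) {
  idx <- which(species(dataset) == speciesTag)
  if (length(idx) == 0)
    stop(sprintf("no records for species '%s'", speciesTag), call. = FALSE)
  sub <- dataset[idx]
  n <- length(sub)
  if (is.null(k)) k <- if (n >= 80) 10L else 5L
  k <- as.integer(k)
  if (2L * k > n)
    stop(sprintf("need at least 2k = %d records for species '%s' (have %d)",
                 2L * k, speciesTag, n), call. = FALSE)
  len <- Biostrings::width(mtsSeqs(sub))
  ord <- order(len, recordId(sub))
  shortIdx <- ord[seq_len(k)]
  longOrd <- order(-len, recordId(sub))
  longIdx <- longOrd[seq_len(k)]
  list(short = sub[shortIdx], long = sub[longIdx])
}

#' Compare two groups of values with a Kruskal-Wallis test
#'
#' Convenience wrapper around [kruskalWallis()] for the two-group
#' short-vs-long MTS comparison of windowed structure proportions.
#'
#' @param shortValues,longValues numeric vectors, each of length >= 2.
#' @return list(`H`, `df`, `p`).
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))
#' @export
compareGroups <- function(shortValues, longValues) {
  if (length(shortValues) < 2 || length(longValues) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  kruskalWallis(list(short = shortValues, long = longValues))
}
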