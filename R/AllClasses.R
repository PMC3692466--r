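#' @import methods
#' @importClassesFrom Biostrings AAStringSet
NULL

#' MtsDataset: species-labelled MTS / mature sequence pairs
#'
#' Container for a dataset of mitochondrial matrix protein records. Each
#' record pairs the N-terminal targeting signal (MTS) with the mature
#' sequence retained after cleavage, plus a species tag and optional gene
#' and accession identifiers. Sequences are stored as
#' [Biostrings::AAStringSet] objects; both parts must be non-empty,
#' uppercase, and drawn from the 20 standard one-letter codes plus the
#' accepted unknown codes (X, B, Z, U, O, J). Record ids are unique.
#'
#' @slot recordId character, unique record identifiers.
#' @slot species character, species tag per record.
#' @slot geneId character, optional gene identifier (`NA` when absent).
#' @slot accession character, optional accession (`NA` when absent).
#' @slot mts AAStringSet of targeting-signal sequences.
#' @slot mature AAStringSet of mature sequences.
#' @slot provenance free-text source note.
#' @slot rejected data.frame (`record_id`, `reason`) describing records
#'   rejected on load.
#'
#' @aliases MtsDataset
#' @exportClass MtsDataset
setClass("MtsDataset",
  representation(
    recordId = "character",
    species = "character",
    geneId = "character",
    accession = "character",
    mts = "AAStringSet",
    mature = "AAStringSet",
    provenance = "character",
    rejected = "data.frame"
  ),
  prototype(
    provenance = "",
    rejected = data.frame(record_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  )
)

setValidity("MtsDataset", function(object) {
  n <- length(object@recordId)
  msgs <- character()
  if (length(object@species) != n || length(object@geneId) != n ||
      length(object@accession) != n || length(object@mts) != n ||
      length(object@mature) != n)
    msgs <- c(msgs, "all per-record slots must have equal length")
  if (anyDuplicated(object@recordId))
    msgs <- c(msgs, "record ids must be unique")
  if (n > 0) {
    if (any(Biostrings::width(object@mts) == 0))
      msgs <- c(msgs, "MTS sequences must be non-empty")
    if (any(Biostrings::width(object@mature) == 0))
      msgs <- c(msgs, "mature sequences must be non-empty")
    bad <- c(vapply(as.character(object@mts),
                    function(s) !is.null(checkAminoSeq(s)), logical(1)),
             vapply(as.character(object@mature),
                    function(s) !is.null(checkAminoSeq(s)), logical(1)))
    if (any(bad))
      msgs <- c(msgs, "sequences must use the standard alphabet plus X,B,Z,U,O,J")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an MtsDataset
#'
#' @param recordId unique record identifiers.
#' @param species species tag per record.
#' @param mts,mature amino-acid strings (or AAStringSet) per record.
#' @param geneId,accession optional identifiers (`NA` where missing).
#' @param provenance free-text source note.
#' @return A validated [MtsDataset-class].
#' @examples
#' d <- MtsDataset(recordId = "r1", species = "Hsap",
#'                 mts = "MAAARSTK", mature = "MKLVNAAD")
#' speciesCounts(d)
#' @export
MtsDataset <- function(recordId, species, mts, mature,
                       geneId = NA_character_, accession = NA_character_,
                       provenance = "") {
  n <- length(recordId)
  mts <- if (is(mts, "AAStringSet")) mts
         else Biostrings::AAStringSet(toupper(as.character(mts)))
  mature <- if (is(mature, "AAStringSet")) mature
            else Biostrings::AAStringSet(toupper(as.character(mature)))
  names(mts) <- names(mature) <- as.character(recordId)
  new("MtsDataset",
      recordId = as.character(recordId),
      species = as.character(rep_len(species, n)),
      geneId = as.character(rep_len(geneId, n)),
      accession = as.character(rep_len(accession, n)),
      mts = mts, mature = mature,
      provenance = provenance)
}

#' SecStructAnnotations: per-residue secondary structure and disorder
#'
#' Per-record annotation of the mature sequence: `ss` is a string over
#' \{H, E, L\} (helix, strand, other) and `disorder` a mask over
#' \{D, .\}, both the same length as the mature sequence they annotate.
#'
#' @slot recordId character, record identifiers.
#' @slot ss character, per-residue states over H/E/L.
#' @slot disorder character, per-residue disorder mask over D/".".
#' @aliases SecStructAnnotations
#' @exportClass SecStructAnnotations
setClass("SecStructAnnotations",
  representation(recordId = "character", ss = "character",
                 disorder = "character"))

setValidity("SecStructAnnotations", function(object) {
  msgs <- character()
  n <- length(object@recordId)
  if (length(object@ss) != n || length(object@disorder) != n)
    msgs <- c(msgs, "recordId, ss and disorder must have equal length")
  if (anyDuplicated(object@recordId))
    msgs <- c(msgs, "record ids must be unique")
  if (n > 0) {
    if (any(nchar(object@ss) != nchar(object@disorder)))
      msgs <- c(msgs, "ss and disorder strings must have equal length per record")
    if (any(grepl("[^HEL]", object@ss)))
      msgs <- c(msgs, "ss states must be H, E or L")
    if (any(grepl("[^D.]", object@disorder)))
      msgs <- c(msgs, "disorder states must be D or '.'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SecStructAnnotations object
#'
#' @param recordId record identifiers.
#' @param ss per-residue H/E/L strings.
#' @param disorder per-residue D/"." masks.
#' @return A validated [SecStructAnnotations-class].
#' @export
SecStructAnnotations <- function(recordId = character(),
                                 ss = character(),
                                 disorder = character()) {
  new("SecStructAnnotations", recordId = as.character(recordId),
      ss = as.character(ss), disorder = as.character(disorder))
}

#' CorrelationResult: an MTS-by-mature grid of Spearman correlations
#'
#' Rectangular grid of rank-correlation cells between MTS-side variables
#' (rows) and mature-side variables (columns), for one grouping (a species
#' tag or `"pooled"`). Cells hold rho, the two-tailed p, the pair count n,
#' and a significance class (`none`, `p<0.05`, `p<0.01`). Cells with fewer
#' than the minimum pair count, or zero variance, are `NA` ("not computed").
#'
#' @slot rho numeric matrix of Spearman's rho.
#' @slot p numeric matrix of two-tailed p-values.
#' @slot n integer matrix of pair counts.
#' @slot sigClass character matrix over none / p<0.05 / p<0.01 / NA.
#' @slot grouping species tag or "pooled".
#' @slot minN minimum pair count used.
#' @aliases CorrelationResult
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(rho = "matrix", p = "matrix", n = "matrix",
                 sigClass = "matrix", grouping = "character",
                 minN = "numeric"))

setValidity("CorrelationResult", function(object) {
  msgs <- character()
  d <- dim(object@rho)
  for (s in c("p", "n", "sigClass"))
    if (!identical(dim(slot(object, s)), d))
      msgs <- c(msgs, sprintf("slot '%s' must match dim(rho)", s))
  if (anyDuplicated(rownames(object@rho)) ||
      anyDuplicated(colnames(object@rho)))
    msgs <- c(msgs, "row and column labels must be unique")
  ok <- abs(object@rho) <= 1 + 1e-12
  if (!all(ok | is.na(object@rho)))
    msgs <- c(msgs, "|rho| must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' PcaSummary: eigenstructure of a standardized property table
#'
#' PCA on the sample correlation matrix of a property table: eigenvalues
#' in descending order, percent and cumulative variance, SPSS-style
#' component loadings (eigenvector times sqrt(eigenvalue), i.e. the
#' variable-component correlations) and the number of components retained
#' under the active rule (Kaiser: eigenvalue strictly greater than 1).
#'
#' @slot eigenvalues numeric, descending, non-negative.
#' @slot percentVar numeric, percent of variance per component.
#' @slot cumulativeVar numeric, cumulative percent.
#' @slot loadings numeric matrix, variable x component.
#' @slot retained integer, components kept by the retention rule.
#' @slot rule retention rule label.
#' @aliases PcaSummary
#' @exportClass PcaSummary
setClass("PcaSummary",
  representation(eigenvalues = "numeric", percentVar = "numeric",
                 cumulativeVar = "numeric", loadings = "matrix",
                 retained = "integer", rule = "character"))

setValidity("PcaSummary", function(object) {
  msgs <- character()
  if (any(object@eigenvalues < -1e-8))
    msgs <- c(msgs, "eigenvalues must be non-negative")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msgs <- c(msgs, "eigenvalues must be in descending order")
  if (abs(sum(object@percentVar) - 100) > 1e-6)
    msgs <- c(msgs, "percent variance must sum to 100")
  if (length(msgs)) msgs else TRUE
})
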