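#' @describeIn MtsDataset-class record identifiers.
#' @export
setMethod("recordId", "MtsDataset", function(x) x@recordId)

#' @describeIn MtsDataset-class species tags.
#' @export
setMethod("species", "MtsDataset", function(x) x@species)

#' @describeIn MtsDataset-class gene identifiers (`NA` where absent).
#' @export
setMethod("geneId", "MtsDataset", function(x) x@geneId)

#' @describeIn MtsDataset-class accessions (`NA` where absent).
#' @export
setMethod("accession", "MtsDataset", function(x) x@accession)

#' @describeIn MtsDataset-class MTS sequences as an AAStringSet.
#' @export
setMethod("mtsSeqs", "MtsDataset", function(x) x@mts)

#' @describeIn MtsDataset-class mature sequences as an AAStringSet.
#' @export
setMethod("matureSeqs", "MtsDataset", function(x) x@mature)

#' @describeIn MtsDataset-class source note.
#' @export
setMethod("provenance", "MtsDataset", function(x) x@provenance)

#' @describeIn MtsDataset-class records rejected on load.
#' @export
setMethod("rejectedRecords", "MtsDataset", function(x) x@rejected)

#' @describeIn MtsDataset-class per-species record counts (named integer,
#'   sums to `length(x)`).
#' @export
setMethod("speciesCounts", "MtsDataset", function(x) {
  tab <- table(x@species)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

#' @describeIn MtsDataset-class number of records.
#' @export
setMethod("length", "MtsDataset", function(x) length(x@recordId))

#' @describeIn MtsDataset-class subset records (by index, id or logical).
#' @param i index, record id or logical vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MtsDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@recordId)
  if (anyNA(i)) stop("unknown record id in subset", call. = FALSE)
  initialize(x,
             recordId = x@recordId[i], species = x@species[i],
             geneId = x@geneId[i], accession = x@accession[i],
             mts = x@mts[i], mature = x@mature[i])
})

#' @describeIn MtsDataset-class compact summary.
#' @export
setMethod("show", "MtsDataset", function(object) {
  cat(sprintf("MtsDataset with %d record(s)\n", length(object)))
  if (length(object) > 0) {
    cnt <- speciesCounts(object)
    cat("  species:",
        paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
    cat(sprintf("  MTS length: %d-%d; mature length: %d-%d\n",
                min(Biostrings::width(object@mts)),
                max(Biostrings::width(object@mts)),
                min(Biostrings::width(object@mature)),
                max(Biostrings::width(object@mature))))
  }
  if (nrow(object@rejected) > 0)
    cat(sprintf("  %d record(s) rejected on load\n", nrow(object@rejected)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  invisible(NULL)
})

#' Coerce an MtsDataset to a data.frame
#'
#' @param x an [MtsDataset-class].
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame with columns `record_id`, `species`, `gene_id`,
#'   `accession`, `mts_seq`, `mature_seq`.
#' @export
as.data.frame.MtsDataset <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  data.frame(record_id = x@recordId, species = x@species,
             gene_id = x@geneId, accession = x@accession,
             mts_seq = as.character(x@mts),
             mature_seq = as.character(x@mature),
             row.names = row.names, stringsAsFactors = FALSE)
}

#' @describeIn SecStructAnnotations-class record identifiers.
#' @export
setMethod("recordId", "SecStructAnnotations", function(x) x@recordId)

#' @describeIn SecStructAnnotations-class H/E/L strings, named by record.
#' @export
setMethod("ssStrings", "SecStructAnnotations",
          function(x) structure(x@ss, names = x@recordId))

#' @describeIn SecStructAnnotations-class disorder masks, named by record.
#' @export
setMethod("disorderStrings", "SecStructAnnotations",
          function(x) structure(x@disorder, names = x@recordId))

#' @describeIn SecStructAnnotations-class number of annotated records.
#' @export
setMethod("length", "SecStructAnnotations", function(x) length(x@recordId))

#' @describeIn SecStructAnnotations-class subset annotations.
#' @param i index or record id.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SecStructAnnotations", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@recordId)
  if (anyNA(i)) stop("unknown record id in subset", call. = FALSE)
  initialize(x, recordId = x@recordId[i], ss = x@ss[i],
             disorder = x@disorder[i])
})

#' @describeIn SecStructAnnotations-class compact summary.
#' @export
setMethod("show", "SecStructAnnotations", function(object) {
  cat(sprintf("SecStructAnnotations for %d record(s)\n", length(object)))
  invisible(NULL)
})

#' @describeIn CorrelationResult-class compact summary.
#' @param object a CorrelationResult.
#' @export
setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult [%s]: %d x %d cells (min n = %d)\n",
              object@grouping, nrow(object@rho), ncol(object@rho),
              as.integer(object@minN)))
  computed <- sum(!is.na(object@rho))
  sig <- sum(object@sigClass %in% c("p<0.05", "p<0.01"))
  cat(sprintf("  %d computed, %d significant (p<0.05 or p<0.01)\n",
              computed, sig))
  invisible(NULL)
})

#' @describeIn PcaSummary-class compact summary.
#' @param object a PcaSummary.
#' @export
setMethod("show", "PcaSummary", function(object) {
  cat(sprintf("PcaSummary: %d variables, %d component(s) retained (%s)\n",
              nrow(object@loadings), object@retained, object@rule))
  k <- min(5L, length(object@eigenvalues))
  cat("  eigenvalues:",
      paste(sprintf("%.3f", object@eigenvalues[seq_len(k)]), collapse = " "),
      if (length(object@eigenvalues) > k) "..." else "", "\n")
  cat(sprintf("  cumulative variance over retained: %.2f%%\n",
              if (object@retained > 0)
                object@cumulativeVar[object@retained] else 0))
  invisible(NULL)
})

#' Accessors for CorrelationResult and PcaSummary
#'
#' Plain-function accessors for the statistical result containers:
#' `corRho`, `corP`, `corN`, `corSigClass`, `corGrouping` extract the
#' matrices of a [CorrelationResult-class]; `pcaEigenvalues`,
#' `pcaPercentVar`, `pcaCumulativeVar`, `pcaLoadings`, `pcaRetained`
#' extract the slots of a [PcaSummary-class].
#'
#' @param x the result object.
#' @return The corresponding slot.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
corRho <- function(x) x@rho
#' @rdname result-accessors
#' @export
corP <- function(x) x@p
#' @rdname result-accessors
#' @export
corN <- function(x) x@n
#' @rdname result-accessors
#' @export
corSigClass <- function(x) x@sigClass
#' @rdname result-accessors
#' @export
corGrouping <- function(x) x@grouping
#' @rdname result-accessors
#' @export
pcaEigenvalues <- function(x) x@eigenvalues
#' @rdname result-accessors
#' @export
pcaPercentVar <- function(x) x@percentVar
#' @rdname result-accessors
#' @export
pcaCumulativeVar <- function(x) x@cumulativeVar
#' @rdname result-accessors
#' @export
pcaLoadings <- function(x) x@loadings
#' @rdname result-accessors
#' @export
pcaRetained <- function(x) x@retained
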