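#' @rdname MtsDataset-class
#' @param object,x an object.
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname MtsDataset-class
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' @rdname MtsDataset-class
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname MtsDataset-class
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname MtsDataset-class
#' @export
setGeneric("mtsSeqs", function(x) standardGeneric("mtsSeqs"))

#' @rdname MtsDataset-class
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))

#' @rdname MtsDataset-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname MtsDataset-class
#' @export
setGeneric("rejectedRecords", function(x) standardGeneric("rejectedRecords"))

#' @rdname MtsDataset-class
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))

#' @rdname SecStructAnnotations-class
#' @param x an object.
#' @export
setGeneric("ssStrings", function(x) standardGeneric("ssStrings"))

#' @rdname SecStructAnnotations-class
#' @export
setGeneric("disorderStrings", function(x) standardGeneric("disorderStrings"))
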