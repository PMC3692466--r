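# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats cor pt qbeta qnbinom rgamma rnorm rbinom rmultinom
#'   rgeom runif pnorm complete.cases p.adjust cor.test kruskal.test
#'   pchisq sd quantile median
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# The 20 standard residues plus the accepted unknown codes.
STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
UNKNOWN_AA <- c("X", "B", "Z", "U", "O", "J")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Validate one amino-acid string; returns NULL if ok, else a reason string.
checkAminoSeq <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) return("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(STANDARD_AA, UNKNOWN_AA))
  if (length(bad) > 0)
    return(sprintf("invalid residue: %s", paste(bad, collapse = ",")))
  NULL
}

assertAminoSeq <- function(seq, what = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  reason <- checkAminoSeq(seq)
  if (!is.null(reason)) stop(sprintf("%s: %s", what, reason), call. = FALSE)
  invisible(seq)
}

unknownFraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars %in% UNKNOWN_AA)
}
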