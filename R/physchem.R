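#' The nine-group reduced amino-acid alphabet
#'
#' Maps each of the 20 standard residues to one of nine physicochemical
#' groups: non-polar aliphatic \{G,A,V,I,L\} -> `a`; non-polar aromatic
#' \{F,W\} -> `f`; non-polar cyclic \{P\} -> `p`; polar sulphur-containing
#' \{C,M\} -> `c`; polar hydroxyl \{S,T\} -> `s`; polar aromatic \{Y\} ->
#' `y`; polar acidic-amide \{N,Q\} -> `n`; acidic \{D,E\} -> `d`; basic
#' \{R,H,K\} -> `b`. The groups partition the standard alphabet.
#'
#' @return Named character vector mapping residue -> group code.
#' @examples
#' reducedAlphabet()[["R"]]
#' @export
reducedAlphabet <- function() {
  map <- c(
    G = "a", A = "a", V = "a", I = "a", L = "a",
    F = "f", W = "f",
    P = "p",
    C = "c", M = "c",
    S = "s", T = "s",
    Y = "y",
    N = "n", Q = "n",
    D = "d", E = "d",
    R = "b", H = "b", K = "b"
  )
  stopifnot(setequal(names(map), STANDARD_AA))
  map
}

#' Group codes of the reduced alphabet, in canonical order
#' @return Character vector of the nine group codes.
#' @export
groupCodes <- function() c("a", "f", "p", "c", "s", "y", "n", "d", "b")

#' Convert a sequence to the reduced alphabet
#'
#' Each standard residue is replaced by its group code; unknown residues
#' (X, B, Z, U, O, J) become `?`. Length is preserved.
#'
#' @param seq amino-acid string (uppercase standard alphabet + unknowns).
#' @param map residue -> group mapping, default [reducedAlphabet()].
#' @return The reduced string, same number of characters as `seq`.
#' @examples
#' reduceSequence("GAVIL")  # "aaaaa"
#' @export
reduceSequence <- function(seq, map = reducedAlphabet()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  assertAminoSeq(seq)
  chartr(paste(c(names(map), UNKNOWN_AA), collapse = ""),
         paste(c(unname(map), rep("?", length(UNKNOWN_AA))), collapse = ""),
         seq)
}

#' Nine-group composition of a sequence
#'
#' Fraction of classified residues falling in each reduced-alphabet group.
#' Unknown residues are excluded from both numerator and denominator, so
#' the nine fractions always sum to 1.
#'
#' @inheritParams reduceSequence
#' @return Named numeric vector `frac_a` ... `frac_b` (canonical group
#'   order), summing to 1.
#' @examples
#' groupComposition("RKDESTAA")
#' @export
groupComposition <- function(seq, map = reducedAlphabet()) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  red <- strsplit(reduceSequence(seq, map), "", fixed = TRUE)[[1]]
  red <- red[red != "?"]
  if (length(red) == 0)
    stop("sequence has no classifiable residues", call. = FALSE)
  counts <- vapply(groupCodes(), function(g) sum(red == g), numeric(1))
  frac <- counts / length(red)
  names(frac) <- paste0("frac_", groupCodes())
  frac
}

# Count ionizable sites of a sequence for a charge model:
# returns list(acidic = counts over D,E,C,Y,cterm; basic = over H,K,R,nterm).
ionizableCounts <- function(seq, includeTermini = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  acidic <- c(D = sum(chars == "D"), E = sum(chars == "E"),
              C = sum(chars == "C"), Y = sum(chars == "Y"),
              cterm = as.numeric(includeTermini))
  basic <- c(H = sum(chars == "H"), K = sum(chars == "K"),
             R = sum(chars == "R"), nterm = as.numeric(includeTermini))
  list(acidic = acidic, basic = basic)
}

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch model: charge = sum over basic sites of
#' 1/(1 + 10^(pH - pKa)) minus sum over acidic sites of
#' 1/(1 + 10^(pKa - pH)), over side chains and (optionally) the free
#' termini. Residues without a pKa contribute 0. Vectorized over `pH`.
#'
#' @param seq amino-acid string.
#' @param pH pH value(s) in (0, 14); default 7.5.
#' @param model a [chargeModel()].
#' @param includeTermini include the N-terminal amine and C-terminal
#'   carboxyl (default TRUE; the mature N-terminus is free after cleavage).
#' @return Net charge in elementary charges, one value per element of `pH`.
#' @examples
#' netCharge("MAAARSTK", pH = 7.5)
#' @export
netCharge <- function(seq, pH = 7.5, model = chargeModel(),
                      includeTermini = TRUE) {
  assertAminoSeq(seq)
  stopifnot(all(pH > 0 & pH < 14))
  cnt <- ionizableCounts(seq, includeTermini)
  vapply(pH, function(ph) {
    pos <- sum(cnt$basic / (1 + 10^(ph - model$basic[names(cnt$basic)])))
    neg <- sum(cnt$acidic / (1 + 10^(model$acidic[names(cnt$acidic)] - ph)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' pH at which the modelled net charge (termini included) crosses zero.
#' Net charge is strictly decreasing in pH and the termini guarantee a
#' sign change on (0, 14), so the root is unique; it is bracketed by
#' bisection to `tol` pH units.
#'
#' @param seq amino-acid string.
#' @param model a [chargeModel()].
#' @param tol bisection tolerance in pH units (default 1e-3).
#' @param maxIter maximum bisection iterations (default 60).
#' @return The isoelectric point in pH units.
#' @examples
#' isoelectricPoint("KKKK") > isoelectricPoint("DDDD")
#' @export
isoelectricPoint <- function(seq, model = chargeModel(), tol = 1e-3,
                             maxIter = 60L) {
  assertAminoSeq(seq)
  cnt <- ionizableCounts(seq, includeTermini = TRUE)
  f <- function(ph) {
    sum(cnt$basic / (1 + 10^(ph - model$basic[names(cnt$basic)]))) -
      sum(cnt$acidic / (1 + 10^(model$acidic[names(cnt$acidic)] - ph)))
  }
  lo <- 0; hi <- 14
  for (i in seq_len(maxIter)) {
    if (hi - lo <= tol) break
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Full physicochemical profile of one sequence
#'
#' Bundles the 12 per-sequence variables used throughout the analysis:
#' residue count (`length`; unknown residues count), net charge at `pH`
#' (`charge`, termini included by default), isoelectric point (`pI`), and
#' the nine reduced-alphabet group fractions.
#'
#' @inheritParams netCharge
#' @param map residue -> group mapping, default [reducedAlphabet()].
#' @return Named numeric vector of length 12:
#'   `length`, `charge`, `pI`, `frac_a` ... `frac_b`.
#' @examples
#' sequenceProperties("MAAARSTK")
#' @export
sequenceProperties <- function(seq, pH = 7.5, map = reducedAlphabet(),
                               model = chargeModel(),
                               includeTermini = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  c(length = nchar(seq),
    charge = netCharge(seq, pH, model, includeTermini),
    pI = isoelectricPoint(seq, model),
    groupComposition(seq, map))
}

#' Canonical names of the 12 per-sequence property variables
#' @return Character vector of length 12.
#' @export
propertyNames <- function() {
  c("length", "charge", "pI", paste0("frac_", groupCodes()))
}

#' Property table for one part of a dataset
#'
#' Computes the 12-variable profile of either the MTS or the mature part
#' of every record in a dataset.
#'
#' @param dataset an [MtsDataset-class].
#' @param part `"mts"` or `"mature"`.
#' @inheritParams sequenceProperties
#' @return A data.frame with columns `record_id`, `species` and the 12
#'   property variables, one row per record, in dataset order.
#' @export
propertyTable <- function(dataset, part = c("mts", "mature"), pH = 7.5,
                          map = reducedAlphabet(), model = chargeModel(),
                          includeTermini = TRUE) {
  part <- match.arg(part)
  seqs <- if (part == "mts") mtsSeqs(dataset) else matureSeqs(dataset)
  seqs <- as.character(seqs)
  props <- t(vapply(seqs, sequenceProperties, numeric(12), pH = pH,
                    map = map, model = model,
                    includeTermini = includeTermini))
  out <- data.frame(record_id = recordId(dataset),
                    species = species(dataset),
                    props, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- propertyNames()
  out
}
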