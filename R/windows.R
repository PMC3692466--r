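#' Specify an N-terminal window of the mature sequence
#'
#' Coordinates are 1-based inclusive, counted from the first residue
#' after the MTS cleavage site. Under policy `require_full` a sequence
#' shorter than `end` yields no window (the record is excluded from that
#' window's statistics); under `truncate` the window is clipped to the
#' sequence end.
#'
#' @param start,end 1-based inclusive bounds, `1 <= start <= end`.
#' @param policy `"require_full"` (default) or `"truncate"`.
#' @return A `WindowSpec` list (`start`, `end`, `policy`).
#' @examples
#' windowSpec(41, 80)
#' @export
windowSpec <- function(start, end, policy = c("require_full", "truncate")) {
  policy <- match.arg(policy)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end)
    stop("window must satisfy 1 <= start <= end", call. = FALSE)
  structure(list(start = start, end = end, policy = policy),
            class = "WindowSpec")
}

#' @export
print.WindowSpec <- function(x, ...) {
  cat(sprintf("WindowSpec %d-%d (%s)\n", x$start, x$end, x$policy))
  invisible(x)
}

#' Extract an N-terminal window from a sequence
#'
#' @param seq amino-acid string (the mature sequence).
#' @param w a [windowSpec()].
#' @return The subsequence, or `NA_character_` when the window is absent
#'   for this sequence under the window's policy.
#' @examples
#' ntermWindow(strrep("A", 100), windowSpec(41, 80))
#' @export
ntermWindow <- function(seq, w) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq),
            inherits(w, "WindowSpec"))
  n <- nchar(seq)
  if (w$policy == "require_full") {
    if (n < w$end) return(NA_character_)
    return(substr(seq, w$start, w$end))
  }
  if (w$start > n) return(NA_character_)
  substr(seq, w$start, min(w$end, n))
}

#' Group fraction within an N-terminal window of the mature sequence
#'
#' Composition fraction of one reduced-alphabet group over the windowed
#' part of a record's mature sequence (e.g. the acidic-residue fraction
#' of mature residues 1-40).
#'
#' @param matureSeq mature amino-acid string.
#' @param w a [windowSpec()].
#' @param group one group code from [groupCodes()].
#' @param map residue -> group mapping, default [reducedAlphabet()].
#' @return The fraction in `[0, 1]`, or `NA_real_` when the window is
#'   absent (such records are dropped pairwise from windowed
#'   correlations).
#' @examples
#' windowedGroupFraction(paste0("DDDD", strrep("K", 36)),
#'                       windowSpec(1, 40), "d")
#' @export
windowedGroupFraction <- function(matureSeq, w, group,
                                  map = reducedAlphabet()) {
  stopifnot(group %in% groupCodes())
  sub <- ntermWindow(matureSeq, w)
  if (is.na(sub)) return(NA_real_)
  unname(groupComposition(sub, map)[paste0("frac_", group)])
}

# Parse "1-40,41-80" into a list of WindowSpec.
parseWindows <- function(text, policy = "require_full") {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    bounds <- suppressWarnings(
      as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]]))
    if (length(bounds) != 2 || anyNA(bounds))
      stop(sprintf("cannot parse window '%s' (expected start-end)", p),
           call. = FALSE)
    windowSpec(bounds[1], bounds[2], policy)
  })
}
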