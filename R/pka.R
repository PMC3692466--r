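#' Henderson-Hasselbalch charge models (pKa sets)
#'
#' A charge model is a named set of pKa values for the ionizable side chains
#' (D, E, C, Y treated as acidic; H, K, R as basic) plus the free N-terminal
#' amine and C-terminal carboxyl. The default set is the Bjellqvist set used
#' by the ExPASy Compute pI/Mw service (with a single generic N-terminal
#' pKa); `emboss` and `lehninger` are the common alternatives. Sets are
#' shipped as a plain-text resource and user files with the same four-column
#' layout (`set`, `site`, `role`, `pka`) can be supplied, so the model is
#' auditable and extensible.
#'
#' @param name name of the pKa set (case-insensitive).
#' @param file optional path to a TSV with columns `set`, `site`, `role`,
#'   `pka`; defaults to the resource shipped with the package.
#' @return An object of class `ChargeModel`: a list with elements `name`,
#'   `acidic` (named pKa vector over D, E, C, Y, cterm) and `basic`
#'   (named pKa vector over H, K, R, nterm).
#' @examples
#' m <- chargeModel("bjellqvist")
#' m$basic[["R"]]
#' @export
chargeModel <- function(name = "bjellqvist", file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pka_sets.tsv", package = "mtsprofiler",
                        mustWork = TRUE)
  tab <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("set", "site", "role", "pka") %in% names(tab)))
  name <- tolower(name)
  tab <- tab[tolower(tab$set) == name, , drop = FALSE]
  if (nrow(tab) == 0)
    stop(sprintf("unknown pKa set '%s' (available: %s)", name,
                 paste(listPkaSets(file), collapse = ", ")), call. = FALSE)
  if (any(tab$pka <= 0 | tab$pka >= 14))
    stop("all pKa values must lie in (0, 14)", call. = FALSE)
  acidicSites <- c("D", "E", "C", "Y", "cterm")
  basicSites <- c("H", "K", "R", "nterm")
  getSite <- function(site) {
    row <- tab[tab$site == site, ]
    if (nrow(row) != 1)
      stop(sprintf("pKa set '%s': site '%s' must appear exactly once",
                   name, site), call. = FALSE)
    row$pka
  }
  roleOf <- function(site) tab$role[tab$site == site]
  for (s in acidicSites)
    if (roleOf(s) != "acidic")
      stop(sprintf("site '%s' must have role 'acidic'", s), call. = FALSE)
  for (s in basicSites)
    if (roleOf(s) != "basic")
      stop(sprintf("site '%s' must have role 'basic'", s), call. = FALSE)
  model <- list(
    name = name,
    acidic = vapply(acidicSites, getSite, numeric(1)),
    basic = vapply(basicSites, getSite, numeric(1))
  )
  class(model) <- "ChargeModel"
  model
}

#' List the pKa sets available in a resource file
#'
#' @param file optional path to a pKa TSV (see [chargeModel()]).
#' @return Character vector of set names.
#' @export
listPkaSets <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pka_sets.tsv", package = "mtsprofiler",
                        mustWork = TRUE)
  unique(tolower(read.delim(file, stringsAsFactors = FALSE)$set))
}

#' @export
print.ChargeModel <- function(x, ...) {
  cat(sprintf("ChargeModel '%s'\n", x$name))
  cat("  acidic:", paste(sprintf("%s=%.2f", names(x$acidic), x$acidic),
                         collapse = " "), "\n")
  cat("  basic: ", paste(sprintf("%s=%.2f", names(x$basic), x$basic),
                         collapse = " "), "\n")
  invisible(x)
}
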