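#' Spearman's rho for one pair of variables
#'
#' Rho is the product-moment correlation of mid-ranks (so ties are
#' handled); the two-tailed p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom,
#' the behaviour of general statistics packages in the n range typical
#' of per-species protein datasets. `exact = TRUE` switches to the exact
#' null distribution (via [stats::cor.test()]) and is intended for
#' n <= 10. Pairs with a missing value in either variable are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @param minN minimum complete-pair count below which the cell is not
#'   computed (default 5).
#' @param exact use the exact null distribution for the p-value.
#' @return list(`rho`, `p`, `n`, `sigClass`); `rho` and `p` are `NA` and
#'   `sigClass` is `NA` when not computed (n < minN or zero variance).
#' @examples
#' spearmanCell(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearmanCell <- function(x, y, minN = 5, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  notComputed <- list(rho = NA_real_, p = NA_real_, n = n,
                      sigClass = NA_character_)
  if (n < max(3, minN)) return(notComputed)
  if (sd(x) == 0 || sd(y) == 0) return(notComputed)
  rho <- cor(rank(x), rank(y))
  p <- if (exact) {
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = TRUE)$p.value)
  } else if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, sigClass = sigClassOf(p))
}

#' Spearman's rho alone
#'
#' @inheritParams spearmanCell
#' @return The rank correlation, or `NA` when fewer than 3 complete
#'   pairs or zero variance.
#' @export
spearmanRho <- function(x, y) spearmanCell(x, y, minN = 3)$rho

# Raw p -> significance class used in the correlation grids.
sigClassOf <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05" else "none"
}

#' MTS-by-mature correlation matrix
#'
#' Builds the grid of Spearman cells between every MTS-side property
#' (rows) and every mature-side property (columns) for one grouping (a
#' species or `"pooled"`). Tables are aligned on `record_id`; a failure
#' in one cell (too few pairs, zero variance) leaves that cell
#' not-computed and never aborts the matrix.
#'
#' @param mtsProps,matureProps property tables as returned by
#'   [propertyTable()] (columns `record_id`, `species`, then variables),
#'   or plain data.frames of numeric variables with a `record_id` column.
#' @param grouping label stored on the result (default `"pooled"`).
#' @param minN minimum pair count per cell (default 5).
#' @param variables which property columns to correlate (default: all 12).
#' @return A [CorrelationResult-class]; row labels are prefixed `mts_`,
#'   column labels `mature_`.
#' @export
correlationMatrix <- function(mtsProps, matureProps, grouping = "pooled",
                              minN = 5, variables = propertyNames()) {
  stopifnot("record_id" %in% names(mtsProps),
            "record_id" %in% names(matureProps))
  common <- intersect(mtsProps$record_id, matureProps$record_id)
  mtsProps <- mtsProps[match(common, mtsProps$record_id), , drop = FALSE]
  matureProps <- matureProps[match(common, matureProps$record_id), ,
                             drop = FALSE]
  vars <- intersect(variables, intersect(names(mtsProps),
                                         names(matureProps)))
  if (length(vars) == 0) stop("no shared property columns", call. = FALSE)
  nr <- length(vars); nc <- length(vars)
  rho <- p <- matrix(NA_real_, nr, nc,
                     dimnames = list(paste0("mts_", vars),
                                     paste0("mature_", vars)))
  n <- matrix(NA_integer_, nr, nc, dimnames = dimnames(rho))
  sig <- matrix(NA_character_, nr, nc, dimnames = dimnames(rho))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cell <- spearmanCell(mtsProps[[vars[i]]], matureProps[[vars[j]]],
                           minN = minN)
      rho[i, j] <- cell$rho
      p[i, j] <- cell$p
      n[i, j] <- cell$n
      sig[i, j] <- cell$sigClass
    }
  }
  new("CorrelationResult", rho = rho, p = p, n = n, sigClass = sig,
      grouping = grouping, minN = minN)
}

#' Long-format view of a correlation matrix
#'
#' One row per cell: `mts_variable`, `mature_variable`, `rho`, `p`, `n`,
#' `sig_class`, `grouping`, plus a Benjamini-Hochberg adjusted p column
#' (`p_bh`) emitted for transparency only — the significance classes are
#' always derived from the raw p-values, as in the source analysis.
#'
#' @param result a [CorrelationResult-class].
#' @return data.frame in row-major cell order.
#' @export
correlationLong <- function(result) {
  rho <- corRho(result)
  idx <- expand.grid(i = seq_len(nrow(rho)), j = seq_len(ncol(rho)))
  idx <- idx[order(idx$i, idx$j), ]
  p <- corP(result)[cbind(idx$i, idx$j)]
  data.frame(
    mts_variable = rownames(rho)[idx$i],
    mature_variable = colnames(rho)[idx$j],
    rho = rho[cbind(idx$i, idx$j)],
    p = p,
    p_bh = p.adjust(p, method = "BH"),
    n = corN(result)[cbind(idx$i, idx$j)],
    sig_class = corSigClass(result)[cbind(idx$i, idx$j)],
    grouping = corGrouping(result),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test over groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on
#' (number of groups - 1) degrees of freedom, delegating to
#' [stats::kruskal.test()]. The degenerate case where every value across
#' all groups is identical (where the tie correction is undefined) is
#' returned as H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   total n >= 3).
#' @return list(`H`, `df`, `p`).
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.857
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0))
    stop("every group needs at least 1 value", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3)
    stop("need at least 3 values in total", call. = FALSE)
  df <- length(groups) - 1L
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = df, p = 1))
  g <- factor(rep(seq_along(groups), sizes))
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
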