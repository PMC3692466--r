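#' PCA of a standardized property table
#'
#' Principal component analysis on the sample correlation matrix: the
#' property columns are standardized to zero mean and unit variance and
#' the correlation matrix is eigendecomposed. Components are ordered by
#' eigenvalue (descending); percent variance per component is
#' eigenvalue / (number of variables) x 100, so eigenvalues sum to the
#' number of (non-constant) variables. Loadings are SPSS-style component
#' loadings, eigenvector times sqrt(eigenvalue), i.e. the correlation of
#' each variable with each component; components are unrotated. Under
#' the Kaiser rule, components with eigenvalue strictly greater than 1
#' are retained.
#'
#' Rows with missing values are dropped; constant columns are dropped
#' with a warning (their correlation is undefined). Fewer rows than
#' columns is allowed — eigenvalues beyond the rank are (numerically)
#' zero.
#'
#' @param props property table ([propertyTable()] output, or any
#'   data.frame; non-numeric columns such as `record_id`/`species` are
#'   ignored).
#' @param retention `"kaiser"` (default) or `"fixed"`.
#' @param k number of components when `retention = "fixed"`.
#' @param variables which columns to use (default: all numeric columns).
#' @return A [PcaSummary-class].
#' @examples
#' tab <- data.frame(a = rnorm(20), b = rnorm(20))
#' pcaProperties(tab)
#' @export
pcaProperties <- function(props, retention = c("kaiser", "fixed"),
                          k = NULL, variables = NULL) {
  retention <- match.arg(retention)
  numeric_cols <- vapply(props, is.numeric, logical(1))
  x <- as.matrix(props[, numeric_cols, drop = FALSE])
  if (!is.null(variables))
    x <- x[, intersect(variables, colnames(x)), drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2)
    stop("need at least 2 complete rows for PCA", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2)
    stop("need at least 2 non-constant variables for PCA", call. = FALSE)
  cm <- cor(x)
  eig <- eigen(cm, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  nvar <- ncol(x)
  pct <- ev / nvar * 100
  loadings <- eig$vectors %*% diag(sqrt(ev))
  dimnames(loadings) <- list(colnames(x),
                             paste0("PC", seq_len(nvar)))
  retained <- if (retention == "kaiser") {
    sum(ev > 1)
  } else {
    if (is.null(k)) stop("retention = 'fixed' requires k", call. = FALSE)
    min(as.integer(k), nvar)
  }
  new("PcaSummary", eigenvalues = ev, percentVar = pct,
      cumulativeVar = cumsum(pct), loadings = loadings,
      retained = as.integer(retained),
      rule = if (retention == "kaiser") "kaiser (eigenvalue > 1)"
             else sprintf("fixed k = %d", retained))
}

#' Tabular summaries of a PCA
#'
#' @param x a [PcaSummary-class].
#' @return `pcaSummaryTable`: data.frame with `component`, `eigenvalue`,
#'   `percent_variance`, `cumulative_percent`, `retained`;
#'   `pcaLoadingsTable`: data.frame of loadings with a leading
#'   `variable` column.
#' @export
pcaSummaryTable <- function(x) {
  nv <- length(pcaEigenvalues(x))
  data.frame(component = paste0("PC", seq_len(nv)),
             eigenvalue = pcaEigenvalues(x),
             percent_variance = pcaPercentVar(x),
             cumulative_percent = pcaCumulativeVar(x),
             retained = seq_len(nv) <= pcaRetained(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname pcaSummaryTable
#' @export
pcaLoadingsTable <- function(x) {
  l <- pcaLoadings(x)
  data.frame(variable = rownames(l), l, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
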