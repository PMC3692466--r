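#' Run the full MTS/mature analysis
#'
#' Orchestrates every stage over one dataset: (1) the per-record
#' 12-variable property table for both parts; (2) per-species and pooled
#' MTS-by-mature Spearman correlation matrices with significance
#' classes; (3) per-species MTS-only PCA plus a combined MTS+mature PCA
#' over all records; (4) the windowed correlation table (MTS length and
#' MTS charge against the acidic-residue fraction of N-terminal mature
#' windows, per species and window); (5) when annotations are supplied,
#' the secondary-structure comparison between shortest- and longest-MTS
#' groups (helix/strand/disorder proportions per analysis window,
#' Kruskal-Wallis H and p); and (6) a run manifest recording every
#' tunable that affects the numbers. A stage that cannot run for a
#' subset (too few records, missing annotations) is skipped with a
#' warning; the rest of the bundle is still produced.
#'
#' @param dataset an [MtsDataset-class].
#' @param annotations optional [SecStructAnnotations-class].
#' @param outDir output directory for the TSV bundle; `NULL` skips
#'   writing and just returns the results.
#' @param pH pH for the charge variable (default 7.5).
#' @param pkaSet name of the pKa set (default `"bjellqvist"`).
#' @param windows list of windowed-analysis [windowSpec()]s (default
#'   1-40 and 41-80, policy `require_full`).
#' @param ssWindows list of secondary-structure windows (default 1-50
#'   and 51-100, truncated).
#' @param extremeK group size for the short/long MTS comparison; `NULL`
#'   uses 10 for species with >= 80 records, else 5.
#' @param minN minimum pair count per correlation cell (default 5).
#' @param digits significant digits for written tables (default 6).
#' @return (invisibly when writing) a list with elements
#'   `properties` (data.frame), `correlations` (named list of
#'   [CorrelationResult-class], per species plus `"pooled"`),
#'   `correlationsLong` (data.frame), `pcaMts` (named list of
#'   [PcaSummary-class] per species), `pcaCombined` ([PcaSummary-class]),
#'   `windowedCorrelations` (data.frame), `ssComparison` (data.frame or
#'   `NULL`), `manifest` (character vector).
#' @export
runFullAnalysis <- function(dataset, annotations = NULL, outDir = NULL,
                            pH = 7.5, pkaSet = "bjellqvist",
                            windows = list(windowSpec(1, 40),
                                           windowSpec(41, 80)),
                            ssWindows = list(
                              windowSpec(1, 50, "truncate"),
                              windowSpec(51, 100, "truncate")),
                            extremeK = NULL, minN = 5, digits = 6) {
  stopifnot(is(dataset, "MtsDataset"), length(dataset) > 0)
  model <- chargeModel(pkaSet)
  map <- reducedAlphabet()

  mtsProps <- propertyTable(dataset, "mts", pH = pH, map = map,
                            model = model)
  matProps <- propertyTable(dataset, "mature", pH = pH, map = map,
                            model = model)
  properties <- merge(mtsProps, matProps, by = c("record_id", "species"),
                      suffixes = c("_mts", "_mature"), sort = FALSE)
  properties <- properties[match(recordId(dataset),
                                 properties$record_id), ]

  groupings <- c(sort(unique(species(dataset))), "pooled")
  correlations <- list()
  for (grp in groupings) {
    keep <- if (grp == "pooled") rep(TRUE, nrow(mtsProps))
            else mtsProps$species == grp
    correlations[[grp]] <- correlationMatrix(
      mtsProps[keep, , drop = FALSE], matProps[keep, , drop = FALSE],
      grouping = grp, minN = minN)
  }
  correlationsLong <- do.call(rbind, lapply(correlations,
                                            correlationLong))
  rownames(correlationsLong) <- NULL
  if (all(is.na(correlationsLong$rho)))
    warning("all correlation cells not-computed (pair counts below minN)",
            call. = FALSE)

  pcaMts <- list()
  for (grp in sort(unique(species(dataset)))) {
    sub <- mtsProps[mtsProps$species == grp, , drop = FALSE]
    pcaMts[[grp]] <- tryCatch(pcaProperties(sub),
                              error = function(e) {
                                warning(sprintf("MTS PCA skipped for %s: %s",
                                                grp, conditionMessage(e)),
                                        call. = FALSE)
                                NULL
                              })
  }
  combined <- properties[, setdiff(names(properties),
                                   c("record_id", "species"))]
  pcaCombined <- tryCatch(pcaProperties(combined),
                          error = function(e) {
                            warning(sprintf("combined PCA skipped: %s",
                                            conditionMessage(e)),
                                    call. = FALSE)
                            NULL
                          })

  windowedCorrelations <- windowedCorrelationTable(
    dataset, mtsProps, windows, map = map, minN = minN)

  ssComparison <- NULL
  if (!is.null(annotations) && length(annotations) > 0) {
    ssComparison <- ssComparisonTable(dataset, annotations, ssWindows,
                                      extremeK = extremeK)
  } else if (!is.null(annotations)) {
    warning("empty annotation set; secondary-structure stage skipped",
            call. = FALSE)
  }

  manifest <- c(
    sprintf("mtsprofiler version: %s",
            as.character(packageVersion("mtsprofiler"))),
    sprintf("records: %d", length(dataset)),
    sprintf("species counts: %s",
            paste(sprintf("%s=%d", names(speciesCounts(dataset)),
                          speciesCounts(dataset)), collapse = " ")),
    sprintf("provenance: %s", provenance(dataset)),
    sprintf("rejected on load: %d", nrow(rejectedRecords(dataset))),
    sprintf("pKa set: %s", model$name),
    sprintf("pH for charge: %g", pH),
    "termini ionized: TRUE",
    sprintf("windowed analysis windows: %s",
            paste(vapply(windows, function(w)
              sprintf("%d-%d(%s)", w$start, w$end, w$policy),
              character(1)), collapse = ", ")),
    sprintf("secondary-structure windows: %s",
            paste(vapply(ssWindows, function(w)
              sprintf("%d-%d(%s)", w$start, w$end, w$policy),
              character(1)), collapse = ", ")),
    sprintf("extreme-group k: %s",
            if (is.null(extremeK)) "auto (10 if n>=80 else 5)"
            else as.character(extremeK)),
    sprintf("minimum pairs per correlation cell: %d", as.integer(minN)),
    "PCA retention: kaiser (eigenvalue > 1), unrotated",
    sprintf("annotations: %s",
            if (is.null(annotations)) "none"
            else sprintf("%d record(s)", length(annotations))))

  result <- list(properties = properties,
                 correlations = correlations,
                 correlationsLong = correlationsLong,
                 pcaMts = pcaMts, pcaCombined = pcaCombined,
                 windowedCorrelations = windowedCorrelations,
                 ssComparison = ssComparison,
                 manifest = manifest)

  if (!is.null(outDir)) {
    writeAnalysisBundle(result, outDir, digits = digits)
    return(invisible(result))
  }
  result
}

# The windowed (Table-1-style) analysis: MTS length and MTS charge vs the
# acidic-group fraction of each N-terminal mature window, per species.
windowedCorrelationTable <- function(dataset, mtsProps, windows,
                                     map = reducedAlphabet(), minN = 5) {
  rows <- list()
  mature <- as.character(matureSeqs(dataset))
  for (w in windows) {
    frac <- vapply(mature, windowedGroupFraction, numeric(1),
                   w = w, group = "d", map = map)
    for (grp in sort(unique(species(dataset)))) {
      keep <- species(dataset) == grp
      for (var in c("length", "charge")) {
        cell <- spearmanCell(mtsProps[[var]][keep], frac[keep],
                             minN = minN)
        rows[[length(rows) + 1]] <- data.frame(
          species = grp,
          window = sprintf("%d-%d", w$start, w$end),
          mts_variable = var,
          mature_variable = "window_frac_d",
          rho = cell$rho, p = cell$p, n = cell$n,
          sig_class = cell$sigClass,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Short-vs-long MTS secondary-structure comparison per species.
ssComparisonTable <- function(dataset, annotations, ssWindows,
                              extremeK = NULL) {
  rows <- list()
  ssAll <- ssStrings(annotations)
  disAll <- disorderStrings(annotations)
  for (grp in sort(unique(species(dataset)))) {
    sub <- dataset[species(dataset) == grp]
    sub <- sub[recordId(sub) %in% recordId(annotations)]
    n <- length(sub)
    k <- if (is.null(extremeK)) (if (n >= 80) 10L else 5L)
         else as.integer(extremeK)
    if (2L * k > n) {
      warning(sprintf(
        "secondary-structure comparison skipped for %s: %d annotated record(s) < 2k = %d",
        grp, n, 2L * k), call. = FALSE)
      next
    }
    groups <- selectExtremeMtsGroups(sub, grp, k = k)
    for (w in ssWindows) {
      propsOf <- function(ids) {
        vals <- lapply(ids, function(id)
          windowSsProportions(ssAll[[id]], disAll[[id]], w))
        vals[!vapply(vals, is.null, logical(1))]
      }
      shortVals <- propsOf(recordId(groups$short))
      longVals <- propsOf(recordId(groups$long))
      for (metric in c("helix", "strand", "disorder")) {
        sv <- vapply(shortVals, `[[`, numeric(1), metric)
        lv <- vapply(longVals, `[[`, numeric(1), metric)
        if (length(sv) < 2 || length(lv) < 2) next
        kw <- compareGroups(sv, lv)
        rows[[length(rows) + 1]] <- data.frame(
          species = grp, window = sprintf("%d-%d", w$start, w$end),
          metric = metric, k = k,
          short_median = median(sv), long_median = median(lv),
          H = kw$H, df = kw$df, p = kw$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Write every table of a result bundle under outDir.
writeAnalysisBundle <- function(result, outDir, digits = 6) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTable(result$properties, file.path(outDir, "properties.tsv"),
             digits = digits)
  writeTable(result$correlationsLong,
             file.path(outDir, "correlations_long.tsv"), digits = digits)
  for (grp in names(result$correlations)) {
    res <- result$correlations[[grp]]
    writeTable(corRho(res),
               file.path(outDir, sprintf("correlation_rho_%s.tsv", grp)),
               digits = digits)
    writeTable(corP(res),
               file.path(outDir, sprintf("correlation_p_%s.tsv", grp)),
               digits = digits)
  }
  for (grp in names(result$pcaMts)) {
    if (is.null(result$pcaMts[[grp]])) next
    writeTable(pcaSummaryTable(result$pcaMts[[grp]]),
               file.path(outDir, sprintf("pca_mts_%s.tsv", grp)),
               digits = digits)
    writeTable(pcaLoadingsTable(result$pcaMts[[grp]]),
               file.path(outDir, sprintf("pca_mts_%s_loadings.tsv", grp)),
               digits = digits)
  }
  if (!is.null(result$pcaCombined)) {
    writeTable(pcaSummaryTable(result$pcaCombined),
               file.path(outDir, "pca_combined.tsv"), digits = digits)
    writeTable(pcaLoadingsTable(result$pcaCombined),
               file.path(outDir, "pca_combined_loadings.tsv"),
               digits = digits)
  }
  writeTable(result$windowedCorrelations,
             file.path(outDir, "windowed_correlations.tsv"),
             digits = digits)
  if (!is.null(result$ssComparison))
    writeTable(result$ssComparison,
               file.path(outDir, "secstruct_comparison.tsv"),
               digits = digits)
  writeLines(result$manifest, file.path(outDir, "manifest.txt"))
  invisible(outDir)
}
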