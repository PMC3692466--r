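# Synthetic MTS/mature datasets with induced rank correlations.
#
# Latent structure: one Gaussian copula dimension ("driver") per sequence
# property named in a target; Spearman targets are converted to latent
# Pearson correlations with the closed form rho_latent = 2 sin(pi rho_S / 6),
# so a target rank correlation is induced (near-)exactly by construction.

#' Segment model for synthetic secondary-structure annotations
#'
#' Mean geometric segment lengths per state, state frequencies, and the
#' per-segment probability of being marked disordered.
#'
#' @param meanLen named numeric, mean segment length for H, E, L (>= 1).
#' @param stateProb named numeric, segment-type frequencies (sum to 1).
#' @param disorderProb per-segment Bernoulli probability of disorder.
#' @return A named list (class `SsSegmentModel`).
#' @export
ssSegmentModel <- function(meanLen = c(H = 9, E = 5, L = 7),
                           stateProb = c(H = 0.35, E = 0.20, L = 0.45),
                           disorderProb = 0.15) {
  stopifnot(setequal(names(meanLen), c("H", "E", "L")),
            setequal(names(stateProb), c("H", "E", "L")),
            all(meanLen >= 1), abs(sum(stateProb) - 1) < 1e-6,
            disorderProb >= 0, disorderProb <= 1)
  structure(list(meanLen = meanLen[c("H", "E", "L")],
                 stateProb = stateProb[c("H", "E", "L")],
                 disorderProb = disorderProb),
            class = "SsSegmentModel")
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the scale and composition structure of curated
#' matrix-protein datasets: five species groups of 85/84/56/35/36
#' records; targeting signals of roughly 10-120 residues whose
#' composition is enriched in basic and hydroxyl residues and deficient
#' in acidic residues; mature sequences near proteome-average
#' composition; and induced rank correlations between MTS and mature
#' properties (by default, MTS length vs mature acidic fraction +0.35
#' and MTS charge vs mature charge -0.437).
#'
#' Targets name a property of each part — `"length"`, `"charge"`, or
#' `"frac_<g>"` for a group code — and the Spearman correlation to
#' induce between them. Each named property is tied to one latent copula
#' dimension; a `length` driver sets the part's length quantile, a
#' `frac_<g>` driver sets group `g`'s residue count to its Beta-marginal
#' quantile, and a `charge` driver moves basic residues up and acidic
#' residues down (or acidic only via its own driver if both are
#' targeted). Two targets may not own the same group of the same part.
#'
#' @param speciesCounts named integer, records per species.
#' @param mtsLength list(`min`, `mean`, `dispersion`): shifted
#'   negative-binomial MTS length model (`min` >= 5).
#' @param matureLength list(`min`, `mean`, `dispersion`) for the mature
#'   part.
#' @param mtsComposition,matureComposition named Dirichlet mean vector
#'   over the nine group codes (positive, summing to 1).
#' @param mtsConcentration,matureConcentration Dirichlet concentration
#'   (total pseudo-count); larger = less between-record variability.
#' @param targets list of `list(mts=, mature=, rho=)` with `|rho| < 1`.
#' @param ssModel a [ssSegmentModel()].
#' @param seed default seed used by [generateDataset()].
#' @return A validated list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(
    speciesCounts = c(Hsap = 85, Mmus = 84, Scer = 56, Atha = 35,
                      Osat = 36),
    mtsLength = list(min = 10, mean = 45, dispersion = 2.5),
    matureLength = list(min = 60, mean = 360, dispersion = 3),
    mtsComposition = c(a = 0.34, f = 0.03, p = 0.05, c = 0.05, s = 0.19,
                       y = 0.01, n = 0.06, d = 0.02, b = 0.25),
    matureComposition = c(a = 0.380, f = 0.050, p = 0.047, c = 0.038,
                          s = 0.118, y = 0.029, n = 0.080, d = 0.122,
                          b = 0.136),
    mtsConcentration = 40,
    matureConcentration = 60,
    targets = list(
      list(mts = "length", mature = "frac_d", rho = 0.35),
      list(mts = "charge", mature = "charge", rho = -0.437)),
    ssModel = ssSegmentModel(),
    seed = 1L) {
  stopifnot(all(speciesCounts >= 0), mtsLength$min >= 5,
            matureLength$min >= 1,
            mtsLength$mean > mtsLength$min,
            matureLength$mean > matureLength$min,
            mtsConcentration > 0, matureConcentration > 0)
  for (comp in list(mtsComposition, matureComposition)) {
    stopifnot(setequal(names(comp), groupCodes()), all(comp > 0),
              abs(sum(comp) - 1) < 1e-6)
  }
  for (t in targets) {
    stopifnot(is.list(t), all(c("mts", "mature", "rho") %in% names(t)),
              abs(t$rho) < 1)
    for (prop in c(t$mts, t$mature))
      if (!(prop %in% c("length", "charge") ||
            prop %in% paste0("frac_", groupCodes())))
        stop(sprintf("unknown target property '%s'", prop), call. = FALSE)
  }
  cfg <- structure(list(
    speciesCounts = speciesCounts,
    mtsLength = mtsLength, matureLength = matureLength,
    mtsComposition = mtsComposition[groupCodes()],
    matureComposition = matureComposition[groupCodes()],
    mtsConcentration = mtsConcentration,
    matureConcentration = matureConcentration,
    targets = targets, ssModel = ssModel, seed = seed),
    class = "GeneratorConfig")
  copulaPlan(cfg)  # errors early on driver conflicts / non-PD structure
  cfg
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat("GeneratorConfig\n")
  cat("  species:", paste(sprintf("%s=%d", names(x$speciesCounts),
                                  x$speciesCounts), collapse = " "), "\n")
  for (t in x$targets)
    cat(sprintf("  target: mts %s ~ mature %s, rho* = %.3f\n",
                t$mts, t$mature, t$rho))
  invisible(x)
}

# Members of each reduced-alphabet group (for sampling residues).
groupMembers <- function() {
  map <- reducedAlphabet()
  split(names(map), unname(map))[groupCodes()]
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

# Resolve the copula structure implied by the targets:
# drivers (part.prop), their latent correlation matrix (PD-checked), and
# which composition groups each driver owns, with tilt direction.
copulaPlan <- function(config) {
  driverIds <- character(0)
  for (t in config$targets)
    driverIds <- union(driverIds,
                       c(paste0("mts.", t$mts), paste0("mature.", t$mature)))
  owned <- list(mts = list(), mature = list())  # group -> direction
  for (id in driverIds) {
    part <- sub("\\..*$", "", id)
    prop <- sub("^[^.]*\\.", "", id)
    if (startsWith(prop, "frac_")) {
      g <- sub("frac_", "", prop)
      if (!is.null(owned[[part]][[g]]))
        stop(sprintf("copula drivers conflict on group '%s' of %s part",
                     g, part), call. = FALSE)
      owned[[part]][[g]] <- list(driver = id, dir = 1)
    }
  }
  for (id in driverIds) {
    part <- sub("\\..*$", "", id)
    prop <- sub("^[^.]*\\.", "", id)
    if (prop == "charge") {
      if (!is.null(owned[[part]][["b"]]))
        stop(sprintf("charge and frac_b drivers conflict on %s part", part),
             call. = FALSE)
      owned[[part]][["b"]] <- list(driver = id, dir = 1)
      if (is.null(owned[[part]][["d"]]))
        owned[[part]][["d"]] <- list(driver = id, dir = -1)
    }
  }
  d <- length(driverIds)
  if (d == 0)
    return(list(drivers = character(0), R = NULL, chol = NULL,
                owned = owned))
  R <- diag(d)
  dimnames(R) <- list(driverIds, driverIds)
  for (t in config$targets) {
    i <- paste0("mts.", t$mts); j <- paste0("mature.", t$mature)
    R[i, j] <- R[j, i] <- 2 * sin(pi * t$rho / 6)
  }
  ch <- tryCatch(chol(R), error = function(e)
    stop("target correlations give a non positive-definite latent structure",
         call. = FALSE))
  list(drivers = driverIds, R = R, chol = ch, owned = owned)
}

# Sample one part's residue counts for all records.
# L: integer vector of lengths; U: matrix of copula uniforms (by driver).
samplePartCounts <- function(L, means, conc, ownedPart, U) {
  n <- length(L)
  counts <- matrix(0L, n, length(groupCodes()),
                   dimnames = list(NULL, groupCodes()))
  fixedGroups <- names(ownedPart)
  for (g in fixedGroups) {
    o <- ownedPart[[g]]
    u <- U[, o$driver]
    if (o$dir < 0) u <- 1 - u
    q <- qbeta(u, conc * means[[g]], conc * (1 - means[[g]]))
    counts[, g] <- as.integer(round(L * q))
  }
  if (length(fixedGroups) > 0) {
    tot <- rowSums(counts[, fixedGroups, drop = FALSE])
    over <- tot > L
    if (any(over)) {  # rare: rescale fixed counts to fit
      for (i in which(over)) {
        cnt <- counts[i, fixedGroups]
        counts[i, fixedGroups] <- as.integer(floor(cnt * L[i] / sum(cnt)))
      }
    }
  }
  freeGroups <- setdiff(groupCodes(), fixedGroups)
  w <- rdirichlet(n, conc * means[freeGroups])
  rem <- L - rowSums(counts)
  for (i in seq_len(n)) {
    if (rem[i] > 0)
      counts[i, freeGroups] <- as.integer(
        rmultinom(1, rem[i], prob = w[i, ]))
  }
  counts
}

# Turn a 9-group count vector into a shuffled residue string.
countsToSequence <- function(counts, members) {
  res <- unlist(lapply(groupCodes(), function(g) {
    k <- counts[[g]]
    if (k == 0) return(character(0))
    sample(members[[g]], k, replace = TRUE)
  }), use.names = FALSE)
  paste(sample(res), collapse = "")
}

#' Generate a synthetic dataset with annotations
#'
#' Draws one latent Gaussian copula vector per record (correlation
#' structure solved from the Spearman targets via
#' rho_latent = 2 sin(pi rho_S / 6)), maps each driver margin to its
#' property — length quantile of the shifted negative binomial, or
#' Beta-marginal residue count of the driven group — samples the
#' remaining composition from the part's Dirichlet model, emits residue
#' strings (residues uniform within groups), and builds segmental
#' secondary-structure annotations for every mature sequence.
#' Reproducible: a fixed seed gives byte-identical output; the caller's
#' RNG state is untouched.
#'
#' @param config a [generatorConfig()].
#' @param seed integer seed (default `config$seed`).
#' @return list(`dataset` = [MtsDataset-class],
#'   `annotations` = [SecStructAnnotations-class]).
#' @examples
#' sim <- generateDataset(generatorConfig(speciesCounts = c(Hsap = 10)))
#' sim$dataset
#' @export
generateDataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"))
  counts <- config$speciesCounts
  n <- sum(counts)
  if (n == 0) {
    return(list(dataset = MtsDataset(character(0), character(0),
                                     character(0), character(0),
                                     provenance = "synthetic (empty)"),
                annotations = SecStructAnnotations()))
  }
  plan <- copulaPlan(config)
  withLocalSeed(seed, {
    d <- length(plan$drivers)
    U <- if (d > 0) {
      Z <- matrix(rnorm(n * d), n, d) %*% plan$chol
      colnames(Z) <- plan$drivers
      pnorm(Z)
    } else {
      matrix(numeric(0), n, 0)
    }
    drawLen <- function(spec, driver) {
      u <- if (driver %in% colnames(U)) U[, driver] else runif(n)
      spec$min + qnbinom(u, size = spec$dispersion,
                         mu = spec$mean - spec$min)
    }
    mtsLen <- drawLen(config$mtsLength, "mts.length")
    matLen <- drawLen(config$matureLength, "mature.length")
    mtsCounts <- samplePartCounts(mtsLen, config$mtsComposition,
                                  config$mtsConcentration,
                                  plan$owned$mts, U)
    matCounts <- samplePartCounts(matLen, config$matureComposition,
                                  config$matureConcentration,
                                  plan$owned$mature, U)
    members <- groupMembers()
    mtsSeq <- vapply(seq_len(n), function(i)
      countsToSequence(mtsCounts[i, ], members), character(1))
    matSeq <- vapply(seq_len(n), function(i)
      countsToSequence(matCounts[i, ], members), character(1))
    speciesVec <- rep(names(counts), counts)
    ids <- sprintf("%s_%03d", speciesVec,
                   unlist(lapply(counts, seq_len), use.names = FALSE))
    ds <- MtsDataset(recordId = ids, species = speciesVec,
                     mts = mtsSeq, mature = matSeq,
                     geneId = sprintf("gene_%04d", seq_len(n)),
                     accession = sprintf("SYN%05d", seq_len(n)),
                     provenance = sprintf(
                       "synthetic (mtsprofiler generator, seed %d)",
                       as.integer(seed)))
    ssRaw <- lapply(matSeq, generateSsAnnotation, model = config$ssModel)
    ann <- SecStructAnnotations(
      recordId = ids,
      ss = vapply(ssRaw, `[[`, character(1), "ss"),
      disorder = vapply(ssRaw, `[[`, character(1), "disorder"))
    list(dataset = ds, annotations = ann)
  })
}

#' Generate one segmental secondary-structure annotation
#'
#' Builds an H/E/L string of the same length as `matureSeq` from
#' geometric-length segments (segment type drawn from the model's state
#' frequencies, length 1 + Geometric with the configured mean) and a
#' disorder mask from independent per-segment Bernoulli draws.
#'
#' @param matureSeq the mature amino-acid string to annotate (only its
#'   length is used).
#' @param model a [ssSegmentModel()].
#' @param seed optional seed for standalone reproducible use; by default
#'   the current RNG stream is consumed.
#' @return list(`ss`, `disorder`), both strings of
#'   `nchar(matureSeq)` characters.
#' @export
generateSsAnnotation <- function(matureSeq, model = ssSegmentModel(),
                                 seed = NULL) {
  stopifnot(inherits(model, "SsSegmentModel"))
  n <- nchar(matureSeq)
  gen <- function() {
    ss <- character(0); dis <- character(0)
    total <- 0L
    states <- names(model$stateProb)
    while (total < n) {
      st <- sample(states, 1, prob = model$stateProb)
      len <- 1L + rgeom(1, prob = 1 / model$meanLen[[st]])
      len <- min(len, n - total)
      ss <- c(ss, rep(st, len))
      mark <- if (rbinom(1, 1, model$disorderProb) == 1) "D" else "."
      dis <- c(dis, rep(mark, len))
      total <- total + len
    }
    list(ss = paste(ss, collapse = ""),
         disorder = paste(dis, collapse = ""))
  }
  if (is.null(seed)) gen() else withLocalSeed(seed, gen())
}
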