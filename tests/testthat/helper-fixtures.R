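# Shared fixtures and independent oracles, built in code at test time.

# Three-record dataset with hand-chosen fields.
makeTinyDataset <- function() {
  MtsDataset(
    recordId = c("r1", "r2", "r3"),
    species = c("Hsap", "Hsap", "Scer"),
    mts = c("MLSRAVCGTSRQLAPALGYLGSRQ", "MAAARSTKLLVRR", "MFSRTSTLLKK"),
    mature = c("ADKNVIGLLDDESRAAKYTEQV", "MKLVNAADPETKKSSED",
               "STAVEQLLDDKNPF"),
    geneId = c("G1", NA, "G3"),
    accession = c("ACC1", "ACC2", NA),
    provenance = "tiny fixture")
}

writeTinyTsv <- function(path) {
  writeDataset(makeTinyDataset(), path)
  path
}

# Independent Henderson-Hasselbalch oracle: its own pKa literals (the
# Bjellqvist table re-typed) and a spreadsheet-style term-by-term sum.
oracleCharge <- function(seq, pH, includeTermini = TRUE) {
  pka <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00,   # acidic
           H = 5.98, K = 10.00, R = 12.00)            # basic
  nterm <- 7.50; cterm <- 3.55
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sum(vapply(chars, function(a) {
    if (a %in% c("H", "K", "R")) 1 / (1 + 10^(pH - pka[[a]])) else 0
  }, numeric(1)))
  neg <- sum(vapply(chars, function(a) {
    if (a %in% c("D", "E", "C", "Y")) 1 / (1 + 10^(pka[[a]] - pH)) else 0
  }, numeric(1)))
  if (includeTermini) {
    pos <- pos + 1 / (1 + 10^(pH - nterm))
    neg <- neg + 1 / (1 + 10^(cterm - pH))
  }
  pos - neg
}

# Vectorized form of the oracle over a pH grid (for the pI grid search).
oracleChargeGrid <- function(seq, grid) {
  pka <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
           H = 5.98, K = 10.00, R = 12.00)
  nterm <- 7.50; cterm <- 3.55
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cnt <- vapply(names(pka), function(a) sum(chars == a), numeric(1))
  pos <- cnt[["H"]] / (1 + 10^(grid - pka[["H"]])) +
    cnt[["K"]] / (1 + 10^(grid - pka[["K"]])) +
    cnt[["R"]] / (1 + 10^(grid - pka[["R"]])) +
    1 / (1 + 10^(grid - nterm))
  neg <- cnt[["D"]] / (1 + 10^(pka[["D"]] - grid)) +
    cnt[["E"]] / (1 + 10^(pka[["E"]] - grid)) +
    cnt[["C"]] / (1 + 10^(pka[["C"]] - grid)) +
    cnt[["Y"]] / (1 + 10^(pka[["Y"]] - grid)) +
    1 / (1 + 10^(cterm - grid))
  pos - neg
}

# Grid-search pI oracle at the given resolution.
oraclePi <- function(seq, resolution = 1e-4) {
  grid <- seq(0, 14, by = resolution)
  grid[which.min(abs(oracleChargeGrid(seq, grid)))]
}

# Classical rank formula for tie-free data: 1 - 6 sum(d^2) / (n(n^2-1)).
oracleSpearmanTieFree <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

randomAaSeq <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}
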