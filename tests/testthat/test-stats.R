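test_that("Spearman cells reproduce the rank formula on tie-free data", {
  expect_equal(spearmanCell(1:4, c(2, 4, 6, 8), minN = 4)$rho, 1)
  expect_equal(spearmanCell(1:4, c(8, 6, 4, 2), minN = 4)$rho, -1)
  # worked example: ranks differ by d = (0,-1,1,-1,1), sum d^2 = 4
  x <- 1:5; y <- c(1, 3, 2, 5, 4)
  expect_equal(oracleSpearmanTieFree(x, y), 0.8)
  expect_equal(spearmanCell(x, y)$rho, 0.8)
  set.seed(41)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    a <- sample(n); b <- rnorm(n)
    expect_equal(spearmanCell(a, b)$rho, oracleSpearmanTieFree(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Spearman p-values match the t approximation used by cor.test", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(8:60, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    cell <- spearmanCell(x, y)
    expect_equal(cell$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(cell$p, ref$p.value, tolerance = 1e-9)
  }
  # exact small-sample option
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 1, 4, 3, 6, 5)
  refExact <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(spearmanCell(x, y, exact = TRUE)$p, refExact$p.value)
})

test_that("Spearman is symmetric and monotone-invariant", {
  set.seed(43)
  x <- rnorm(30); y <- rnorm(30) + 0.5 * x
  expect_equal(spearmanCell(x, y)$rho, spearmanCell(y, x)$rho)
  expect_equal(spearmanCell(exp(x), y)$rho, spearmanCell(x, y)$rho)
  expect_equal(spearmanCell(x, y^3 + 10)$rho,
               spearmanCell(x, sign(y) * abs(y))$rho)
})

test_that("degenerate Spearman cells are reported as not computed", {
  cell <- spearmanCell(1:4, c(2, 4, 6, 8))        # below default minN = 5
  expect_true(is.na(cell$rho))
  expect_true(is.na(cell$sigClass))
  cell <- spearmanCell(rep(1, 10), rnorm(10))      # zero variance
  expect_true(is.na(cell$rho))
  # missing values are dropped pairwise
  x <- c(1:6, NA); y <- c(2, 4, 6, 8, 10, 12, 1)
  expect_equal(spearmanCell(x, y)$n, 6)
  expect_equal(spearmanCell(x, y)$rho, 1)
})

test_that("significance classes follow the raw p thresholds", {
  expect_equal(mtsprofiler:::sigClassOf(0.005), "p<0.01")
  expect_equal(mtsprofiler:::sigClassOf(0.03), "p<0.05")
  expect_equal(mtsprofiler:::sigClassOf(0.2), "none")
  expect_true(is.na(mtsprofiler:::sigClassOf(NA_real_)))
})

test_that("the correlation matrix aligns records and survives bad cells", {
  set.seed(44)
  n <- 40
  ids <- sprintf("r%02d", 1:n)
  mts <- data.frame(record_id = ids, species = "Hsap",
                    length = rnorm(n), charge = rnorm(n), pI = rnorm(n))
  mat <- data.frame(record_id = sample(ids), species = "Hsap")
  mat$length <- -mts$length[match(mat$record_id, mts$record_id)]
  mat$charge <- rnorm(n)
  mat$pI <- rep(1, n)                      # constant -> cells not computed
  res <- correlationMatrix(mts, mat, grouping = "Hsap",
                           variables = c("length", "charge", "pI"))
  expect_s4_class(res, "CorrelationResult")
  expect_equal(dim(corRho(res)), c(3, 3))
  # alignment on record_id: length vs length is exactly -1 despite shuffling
  expect_equal(corRho(res)["mts_length", "mature_length"], -1)
  expect_true(all(is.na(corRho(res)[, "mature_pI"])))
  expect_equal(corGrouping(res), "Hsap")
  long <- correlationLong(res)
  expect_equal(nrow(long), 9)
  computed <- !is.na(long$p)
  expect_true(all(long$p_bh[computed] >= long$p[computed] - 1e-12))
  expect_identical(long$sig_class[computed],
                   vapply(long$p[computed], mtsprofiler:::sigClassOf,
                          character(1)))
})

test_that("Kruskal-Wallis matches the tie-corrected rank formula", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1)
  expect_equal(kw$p, 1 - pchisq(kw$H, 1))
  # independent hand computation with tie correction
  g1 <- c(1, 2, 2); g2 <- c(3, 3, 4)
  all <- c(g1, g2); r <- rank(all); N <- 6
  Huncorr <- 12 / (N * (N + 1)) *
    (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * (N + 1)
  ties <- table(all)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  expect_equal(kruskalWallis(list(g1, g2))$H, Huncorr / C,
               tolerance = 1e-12)
  # degenerate and invalid inputs
  kw <- kruskalWallis(list(c(7, 7), c(7, 7, 7)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  expect_error(kruskalWallis(list(c(1, 2, 3))), "2 groups")
  expect_error(kruskalWallis(list(numeric(0), c(1, 2))), "at least 1")
})

test_that("PCA eigenstructure matches independent oracles", {
  # rank-1 case: two perfectly correlated variables
  x <- rnorm(30)
  tab <- data.frame(v1 = x, v2 = 2 * x + 5)
  p <- suppressWarnings(pcaProperties(tab))
  expect_equal(pcaEigenvalues(p), c(2, 0), tolerance = 1e-12)
  expect_equal(pcaPercentVar(p)[1], 100, tolerance = 1e-9)
  # eigenvalues of a fixed correlation matrix vs characteristic polynomial:
  # det(C - lambda I) = -lambda^3 + 3 lambda^2 - 2.62 lambda + 0.68
  C <- matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3)
  X <- MASS::mvrnorm(50, rep(0, 3), C, empirical = TRUE)
  p <- pcaProperties(as.data.frame(X))
  roots <- sort(Re(polyroot(c(-0.68, 2.62, -3, 1))), decreasing = TRUE)
  expect_equal(pcaEigenvalues(p), roots, tolerance = 1e-9)
  # SPSS-style loadings are variable-component correlations
  scores <- scale(X) %*% eigen(cor(X), symmetric = TRUE)$vectors
  expect_equal(abs(cor(scale(X), scores)), abs(pcaLoadings(p)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCA on random tables keeps the correlation-matrix invariants", {
  set.seed(45)
  tab <- as.data.frame(matrix(rnorm(200), 20, 10))
  p <- pcaProperties(tab)
  expect_equal(sum(pcaEigenvalues(p)), 10, tolerance = 1e-9)
  expect_equal(sum(pcaPercentVar(p)), 100, tolerance = 1e-9)
  expect_equal(pcaCumulativeVar(p)[10], 100, tolerance = 1e-9)
  expect_true(all(diff(pcaEigenvalues(p)) <= 1e-12))
  # prcomp as independent cross-check of the decomposition
  pr <- prcomp(tab, scale. = TRUE)
  expect_equal(pcaEigenvalues(p), unname(pr$sdev^2), tolerance = 1e-9)
  # constant columns are dropped with a warning
  tab$const <- 3
  expect_warning(p2 <- pcaProperties(tab), "constant")
  expect_equal(sum(pcaEigenvalues(p2)), 10, tolerance = 1e-9)
  # fewer rows than columns: trailing eigenvalues are numerically zero
  thin <- as.data.frame(matrix(rnorm(5 * 10), 5, 10))
  p3 <- pcaProperties(thin)
  expect_lt(pcaEigenvalues(p3)[10], 1e-9)
  # fixed retention
  expect_equal(pcaRetained(pcaProperties(tab[1:10], retention = "fixed",
                                         k = 3)), 3L)
})
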