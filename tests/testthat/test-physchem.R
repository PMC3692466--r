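test_that("the nine-group reduction maps residues to their groups", {
  expect_identical(reduceSequence("GAVIL"), "aaaaa")
  expect_identical(reduceSequence("RHKDE"), "bbbdd")
  expect_identical(reduceSequence("FWPCMSTYNQ"), "ffpccssynn")
  expect_identical(reduceSequence(""), "")
  expect_identical(reduceSequence("AXB"), "a??")
  map <- reducedAlphabet()
  expect_setequal(names(map),
                  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  expect_setequal(unique(unname(map)), groupCodes())
  set.seed(4)
  for (i in 1:10) {
    s <- randomAaSeq(sample(5:60, 1))
    expect_equal(nchar(reduceSequence(s)), nchar(s))
  }
})

test_that("group composition is the classified-residue fraction per group", {
  comp <- groupComposition("DDEE")
  expect_equal(comp[["frac_d"]], 1)
  expect_equal(sum(comp), 1)
  expect_equal(unname(groupComposition("RKDESTAA")[c("frac_b", "frac_d",
                                                     "frac_s", "frac_a")]),
               rep(0.25, 4))
  # unknowns excluded from numerator and denominator
  expect_equal(groupComposition("DDXX")[["frac_d"]], 1)
  expect_error(groupComposition("XXX"), "no classifiable")
  set.seed(5)
  for (i in 1:10) {
    s <- randomAaSeq(sample(5:60, 1))
    comp <- groupComposition(s)
    expect_equal(sum(comp), 1, tolerance = 1e-12)
    # composition agrees with direct counting on the reduced string
    red <- strsplit(reduceSequence(s), "", fixed = TRUE)[[1]]
    byCode <- vapply(groupCodes(), function(g) mean(red == g), numeric(1))
    expect_equal(unname(comp), unname(byCode))
  }
})

test_that("net charge matches a term-by-term Henderson-Hasselbalch sum", {
  expect_equal(netCharge("DECYKRH", pH = 7.5),
               oracleCharge("DECYKRH", 7.5), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    s <- randomAaSeq(40)
    ph <- runif(1, 2, 12)
    expect_equal(netCharge(s, ph), oracleCharge(s, ph), tolerance = 1e-10)
    expect_equal(netCharge(s, ph, includeTermini = FALSE),
                 oracleCharge(s, ph, includeTermini = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("net charge behaves at the acid asymptote and without ionizable groups", {
  # near pH 0 the N-terminal amine is fully protonated, carboxyl neutral
  expect_equal(netCharge("AAAA", pH = 0.05), 1, tolerance = 0.01)
  # no ionizable side chains + termini off -> exactly zero at every pH
  for (ph in c(1, 4.2, 7.5, 11))
    expect_identical(netCharge("GANQSTPMWF", ph, includeTermini = FALSE), 0)
  # unknown residues contribute no charge
  expect_identical(netCharge("KDX", 7.5, includeTermini = FALSE),
                   netCharge("KD", 7.5, includeTermini = FALSE))
})

test_that("net charge is strictly decreasing in pH", {
  set.seed(7)
  grid <- seq(0.5, 13.5, by = 0.25)
  for (i in 1:10) {
    ch <- netCharge(randomAaSeq(sample(10:60, 1)), grid)
    expect_true(all(diff(ch) < 0))
  }
})

test_that("bisection pI agrees with a 0.0001-resolution grid search", {
  set.seed(8)
  for (i in 1:100) {
    s <- randomAaSeq(50)
    expect_lt(abs(isoelectricPoint(s) - oraclePi(s)), 1e-3 + 1e-4)
  }
})

test_that("pI is ordered by charge content and zeroes the net charge", {
  expect_lt(isoelectricPoint("DDDD"), isoelectricPoint("KKKK"))
  model <- chargeModel()
  piG <- isoelectricPoint("GGGG")
  expect_gt(piG, model$acidic[["cterm"]])
  expect_lt(piG, model$basic[["nterm"]])
  set.seed(9)
  for (i in 1:10) {
    s <- randomAaSeq(30)
    # |f'(pI)| * bisection tolerance bounds the residual charge
    expect_lt(abs(netCharge(s, isoelectricPoint(s))), 0.02)
  }
  expect_lt(abs(netCharge("GGGG", isoelectricPoint("GGGG"))), 1e-3)
})

test_that("sequenceProperties bundles the 12 variables coherently", {
  p <- sequenceProperties("RRRR")
  expect_equal(p[["frac_b"]], 1)
  expect_gt(p[["charge"]], 0)
  p <- sequenceProperties("DDDD")
  expect_equal(p[["frac_d"]], 1)
  expect_lt(p[["charge"]], 0)
  expect_equal(sequenceProperties("MAAARSTK")[["length"]], 8)
  expect_identical(names(sequenceProperties("MAAARSTK")), propertyNames())
  # unknowns count toward length but not composition
  p <- sequenceProperties("DDXX")
  expect_equal(p[["length"]], 4)
  expect_equal(p[["frac_d"]], 1)
})

test_that("pKa sets are named, validated and user-extensible", {
  expect_setequal(listPkaSets(), c("bjellqvist", "emboss", "lehninger"))
  expect_error(chargeModel("nosuchset"), "unknown pKa set")
  m <- chargeModel("emboss")
  expect_equal(m$basic[["K"]], 10.8)
  # pI ranks are stable across shipped sets even if absolute values move
  expect_lt(isoelectricPoint("DDDD", chargeModel("emboss")),
            isoelectricPoint("KKKK", chargeModel("emboss")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("set\tsite\trole\tpka",
               "custom\tnterm\tbasic\t8.0", "custom\tcterm\tacidic\t3.1",
               "custom\tD\tacidic\t4.0", "custom\tE\tacidic\t4.4",
               "custom\tC\tacidic\t9.0", "custom\tY\tacidic\t10.0",
               "custom\tH\tbasic\t6.0", "custom\tK\tbasic\t10.4",
               "custom\tR\tbasic\t12.0"), tf)
  expect_equal(chargeModel("custom", tf)$acidic[["D"]], 4.0)
})
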