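test_that("datasets round-trip exactly through write and read", {
  ds <- makeTinyDataset()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeDataset(ds, tf)
  back <- readDataset(tf)
  expect_identical(recordId(back), recordId(ds))
  expect_identical(species(back), species(ds))
  expect_identical(geneId(back), geneId(ds))
  expect_identical(accession(back), accession(ds))
  expect_identical(as.character(mtsSeqs(back)), as.character(mtsSeqs(ds)))
  expect_identical(as.character(matureSeqs(back)),
                   as.character(matureSeqs(ds)))
  expect_equal(length(back), 3L)
})

test_that("invalid records are rejected with per-record reasons", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- as.data.frame(makeTinyDataset())
  tab$mts_seq[2] <- "MAAAR1TK"        # digit: alphabet violation
  tab$gene_id[is.na(tab$gene_id)] <- "."
  tab$accession[is.na(tab$accession)] <- "."
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ds <- readDataset(tf), "rejected")
  expect_equal(length(ds), 2L)
  rej <- rejectedRecords(ds)
  expect_equal(rej$record_id, "r2")
  expect_match(rej$reason, "invalid residue")
})

test_that("unknown residues are tolerated up to the configured fraction", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  ds <- MtsDataset(c("ok", "bad"), "Hsap",
                   mts = c(paste0("MX", strrep("A", 38)),   # 2.5% unknown
                           paste0("MXXX", strrep("A", 16))), # 15% unknown
                   mature = c(strrep("ADKV", 20), strrep("ADKV", 20)))
  writeDataset(ds, tf)
  expect_warning(back <- readDataset(tf), "rejected")
  expect_equal(recordId(back), "ok")
  expect_match(rejectedRecords(back)$reason, "unknown")
  # sequence case is normalized on load
  writeLines(c("record_id\tspecies\tgene_id\taccession\tmts_seq\tmature_seq",
               "lc\tHsap\t.\t.\tmaaarstk\tmklvnaad"), tf)
  back <- readDataset(tf)
  expect_identical(as.character(mtsSeqs(back)), c(lc = "MAAARSTK"))
})

test_that("file-level problems are errors, not empty datasets", {
  expect_error(readDataset(file.path(tempdir(), "no-such-file.tsv")),
               "does not exist")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("record_id\tspecies\tgene_id\taccession\tmts_seq\tmature_seq",
             tf)
  expect_error(readDataset(tf), "no records")
  writeLines(c("record_id\tspecies\tmts_seq",
               "r1\tHsap\tMAAA"), tf)
  expect_error(readDataset(tf), "missing required column")
  tab <- as.data.frame(makeTinyDataset())
  tab$record_id <- c("r1", "r1", "r3")
  tab$gene_id[is.na(tab$gene_id)] <- "."
  tab$accession[is.na(tab$accession)] <- "."
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readDataset(tf), "duplicate record_id")
})

test_that("precursors split exactly at the cleavage site", {
  expect_equal(splitFullSequence("MAAARSTK", 4),
               list(mts = "MAAA", mature = "RSTK"))
  expect_equal(splitFullSequence("MK", 1), list(mts = "M", mature = "K"))
  expect_error(splitFullSequence("MAAARSTK", 8), "cleavagePos")
  expect_error(splitFullSequence("MAAARSTK", 0), "cleavagePos")
  set.seed(11)
  for (i in 1:20) {
    s <- randomAaSeq(sample(10:80, 1))
    p <- sample(seq_len(nchar(s) - 1), 1)
    parts <- splitFullSequence(s, p)
    expect_identical(paste0(parts$mts, parts$mature), s)
  }
})

test_that("the FASTA pair dialect splits precursors by header cleavage", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 cleavage=4 species=Hsap", "MAAARSTKLLVDDE",
               ">p2 cleavage=6", "MLSRAVCGTSRQ"), tf)
  ds <- readDataset(tf, format = "fasta_pair")
  expect_identical(as.character(mtsSeqs(ds)),
                   c(p1 = "MAAA", p2 = "MLSRAV"))
  expect_identical(as.character(matureSeqs(ds)),
                   c(p1 = "RSTKLLVDDE", p2 = "CGTSRQ"))
  expect_identical(species(ds), c("Hsap", "unknown"))
  writeLines(c(">p1 species=Hsap", "MAAARSTK"), tf)
  expect_error(readDataset(tf, format = "fasta_pair"), "cleavage")
})

test_that("species counts sum to the record total", {
  ds <- makeTinyDataset()
  cnt <- speciesCounts(ds)
  expect_equal(sum(cnt), length(ds))
  expect_equal(cnt[["Hsap"]], 2L)
  sub <- ds["r3"]
  expect_equal(species(sub), "Scer")
})

test_that("writeTable writes rounded rectangular TSVs that round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(row = c("a", "b"), x = c(1.23456789, 2),
                    y = c(3.14159265, 0.000123456789))
  writeTable(tab, tf)
  expect_equal(length(readLines(tf)), 3L)  # header + 2 rows
  back <- read.delim(tf)
  expect_equal(back$x, signif(tab$x, 6))
  expect_equal(back$y, signif(tab$y, 6))
  expect_identical(back$row, tab$row)
  # empty table -> header-only file
  writeTable(tab[0, ], tf)
  expect_equal(length(readLines(tf)), 1L)
  # matrices gain a leading label column
  m <- matrix(1:4, 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  writeTable(m, tf)
  expect_identical(read.delim(tf)$row, c("r1", "r2"))
})
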