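test_that("design TSV and FASTA round-trip a full design", {
  ag <- agilentSeries(replicateCount = 60, seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDesignTSV(ag$design, tsv)
  back <- readDesignTSV(tsv)
  expect_identical(templates(back), templates(ag$design))
  expect_equal(replicateCount(back), 60)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeDesignFASTA(ag$design, fa)
  seqs <- readFASTA(fa)
  expect_identical(unname(seqs), templates(ag$design)$full_sequence)
  expect_identical(names(seqs), probeIds(ag$design))
})

test_that("chimera TSV round-trips segments, chemistry and labels", {
  oligos <- list(
    primer = defaultPrimer()@oligo,
    product = chimericOligo(c("UAGGGACACGGCGAA", "GGAAAUUGGACCUGGGUUGA"),
                            c("OMe", "RNA"), label5 = "psoralen"),
    template = chimericOligo("TCAACCCAGGTCCAATTTCC", "DNA",
                             label3 = "surface"))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeChimeraTSV(oligos, p)
  back <- readChimeraTSV(p)
  expect_identical(names(back), names(oligos))
  for (nm in names(oligos)) {
    expect_identical(oligoSegments(back[[nm]]), oligoSegments(oligos[[nm]]))
    expect_identical(back[[nm]]@label5, oligos[[nm]]@label5)
    expect_identical(back[[nm]]@label3, oligos[[nm]]@label3)
  }
  expect_error(readChimeraTSV(withr::local_tempfile(lines = "bogus")),
               "line 1")
})

test_that("GAL files use 1-based GenePix coordinates and round-trip layouts", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    ids <- sprintf("probe%02d", seq_len(n))
    layout <- gridLayout(sample(ids), 4, 4)
    p <- withr::local_tempfile(fileext = ".gal")
    writeGAL(layout, path = p)
    back <- readGAL(p, nRows = 4, nCols = 4)
    expect_identical(layoutFeatures(back)[c("row", "col", "probe_id")],
                     layoutFeatures(layout)[c("row", "col", "probe_id")])
  }
  layout <- gridLayout(c("a", "b", "c"), 2, 2)
  p <- withr::local_tempfile(fileext = ".gal")
  writeGAL(layout, path = p)
  lines <- readLines(p)
  expect_identical(lines[1], "ATF\t1.0")
  body <- lines[-(1:4)]
  # feature at 0-based (row 1, col 0) is written Block 1, Column 1, Row 2
  expect_true(any(grepl("^1\t1\t2\t", body)))
})

test_that("GPR subset round-trips per-channel intensities", {
  set.seed(67)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    d <- do.call(rbind, lapply(c("532", "635"), function(ch)
      data.frame(row = rep(0:(n - 1)), col = 0L,
                 probe_id = sprintf("p%d", seq_len(n)), channel = ch,
                 F = round(runif(n, 0, 65535), 1),
                 B = round(runif(n, 0, 500), 1), stringsAsFactors = FALSE)))
    scan <- scanTable(d, arm = "sim")
    p <- withr::local_tempfile(fileext = ".gpr")
    writeGPR(scan, p)
    back <- scanData(readGPR(p))
    key <- function(x) x[order(x$channel, x$row, x$col), ]
    a <- key(d); b <- key(back)
    expect_equal(b$F, a$F, tolerance = 1e-5)
    expect_equal(b$B, a$B, tolerance = 1e-5)
    expect_identical(b$probe_id, a$probe_id)
    expect_identical(sort(unique(b$channel)), c("532", "635"))
  }
})

test_that("GPR parsing reports dialect problems precisely", {
  p <- withr::local_tempfile(lines = c("ATF\t2.0", "1\t5",
                                       "\"Type=GenePix Results 3\"",
                                       "Block\tColumn\tRow\tName\tID"))
  expect_error(readGPR(p), "unsupported ATF version '2.0'")
  p2 <- withr::local_tempfile(lines = c("not a gpr"))
  expect_error(readGPR(p2), "not an ATF file")
  p3 <- withr::local_tempfile(lines = c("ATF\t1.0", "1\t4",
                                        "\"Type=GenePix Results 3\"",
                                        "Block\tColumn\tRow\tID",
                                        "1\t1\t1\tx"))
  expect_error(readGPR(p3), "F<wavelength> Median")
})

test_that("plain scan TSV round-trips", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    d <- data.frame(row = 0:(n - 1), col = rep(0L, n),
                    probe_id = sprintf("p%d", 1:n), channel = "532",
                    F = round(runif(n, 0, 1e4), 2), B = rep(10.5, n),
                    stringsAsFactors = FALSE)
    p <- withr::local_tempfile(fileext = ".tsv")
    writeScanTSV(scanTable(d), p)
    back <- scanData(readScanTSV(p))
    expect_equal(back$F, d$F, tolerance = 1e-5)
    expect_identical(back$probe_id, d$probe_id)
  }
})

test_that("PPM images round-trip byte-exactly; 2x2 P6 parses to exact values", {
  set.seed(73)
  for (i in 1:25) {
    h <- sample(1:6, 1); w <- sample(1:6, 1)
    img <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
    p <- withr::local_tempfile(fileext = ".ppm")
    writePPM(img, p)
    expect_identical(readPPM(p), array(as.integer(img), dim(img)))
  }
  # hand-written 2x2 P6 with known bytes
  p <- withr::local_tempfile(fileext = ".ppm")
  con <- file(p, "wb")
  writeChar("P6\n2 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(255, 0, 0,  0, 255, 0,  0, 0, 255,  10, 20, 30)), con)
  close(con)
  img <- readPPM(p)
  expect_identical(img[1, 1, ], c(255L, 0L, 0L))
  expect_identical(img[1, 2, ], c(0L, 255L, 0L))
  expect_identical(img[2, 1, ], c(0L, 0L, 255L))
  expect_identical(img[2, 2, ], c(10L, 20L, 30L))
  expect_error(readPPM(withr::local_tempfile(lines = "P5 junk")), "P3/P6")
})

test_that("PBM masks round-trip in binary and ASCII at awkward widths", {
  set.seed(79)
  for (i in 1:25) {
    h <- sample(1:9, 1); w <- sample(c(1:9, 15, 17), 1)
    m <- matrix(runif(h * w) > 0.5, h, w)
    for (ascii in c(TRUE, FALSE)) {
      p <- withr::local_tempfile(fileext = ".pbm")
      writePBM(m, p, ascii = ascii)
      expect_identical(readPBM(p), m)
    }
  }
})

test_that("synthesis plans export masks plus a readable manifest", {
  design <- rawDesign(c("f1", "f2"), c("ACGT", "TTAC"), linkerLens = 0L)
  layout <- gridLayout(c("f1", "f2"), 1, 2)
  plan <- scheduleSynthesis(layout, design)
  dir <- withr::local_tempdir()
  manifest <- writeSynthesisPlan(plan, dir)
  mf <- readCycleManifest(manifest)
  cy <- planCycles(plan)
  expect_equal(nrow(mf), nrow(cy))
  expect_identical(mf$monomer, cy$monomer)
  for (i in which(!is.na(cy$mask))) {
    m <- readPBM(file.path(dir, paste0(cy$mask[i], ".pbm")))
    expect_identical(m, planMasks(plan)[[cy$mask[i]]])
  }
})

test_that("YAML config round-trips", {
  cfg <- list(platform = "inkjet", primer = "Ps-OMe15", seed = 7L,
              replicate_count = 60L)
  p <- withr::local_tempfile(fileext = ".yaml")
  writeConfig(cfg, p)
  expect_equal(readConfig(p), cfg)
})

test_that("quantification reports write TSV plus JSON summary", {
  st <- aggregateScan(scanTable(data.frame(
    row = 0L, col = 0:4, probe_id = "p", channel = "532",
    F = c(10, 12, 14, 16, 18), B = 0, stringsAsFactors = FALSE)))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeQuantReport(st, p, summary = list(mean_intensity = 14))
  lines <- readLines(p)
  expect_match(lines[1], "^probe_id\tchannel\tn\tmean")
  js <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(js$mean_intensity, 14)
})
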