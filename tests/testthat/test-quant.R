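mkScan <- function(values, probe = "p", channel = "532") {
  n <- length(values)
  scanTable(data.frame(row = rep(0L, n), col = seq_len(n) - 1L,
                       probe_id = probe, channel = channel,
                       F = values, B = 0, stringsAsFactors = FALSE))
}

test_that("replicate aggregation: mean/sd, permutation invariance, dust rule", {
  st <- aggregateScan(mkScan(c(10, 20, 30)))
  expect_equal(st$mean, 20)
  expect_equal(st$sd, 10)
  expect_equal(st$n, 3)
  expect_equal(st$n_excluded, 0)
  stPerm <- aggregateScan(mkScan(c(30, 10, 20)))
  expect_equal(stPerm[c("mean", "sd", "n")], st[c("mean", "sd", "n")])
  # 85 replicates with 2 dust specks at 100x: the MAD rule excludes exactly those
  set.seed(11)
  vals <- rlnorm(85, log(1000), 0.2)
  vals[c(7, 41)] <- vals[c(7, 41)] * 100
  stD <- aggregateScan(mkScan(vals), excludeOutliers = TRUE, madLimit = 5)
  expect_equal(stD$n_excluded, 2)
  expect_equal(stD$n, 83)
  expect_lt(stD$mean, 2000)
  # rule off by default
  expect_equal(aggregateScan(mkScan(vals))$n_excluded, 0)
})

test_that("aggregation flags design probes missing from the scan", {
  design <- designTable(list(makeTemplate("ACGTACGT", 5, probeId = "here"),
                             makeTemplate("GGTTCCAA", 5, probeId = "gone")))
  scan <- mkScan(c(5, 6), probe = "here")
  expect_warning(st <- aggregateScan(scan, design), "gone")
  expect_equal(st$probe_id, "here")
  expect_error(aggregateScan(mkScan(1:3, probe = "alien"), design),
               "not in the design")
})

test_that("control subtraction and max-normalization follow the published recipe", {
  out <- backgroundCorrectNormalize(c(a = 100, b = 80), c(ca = 20, cb = 20),
                                    data.frame(template = c("a", "b"),
                                               control = c("ca", "cb")))
  expect_equal(out$corrected, c(80, 60))
  expect_equal(out$normalized, c(1.0, 0.75))
  # template below its control floors at 0
  fl <- backgroundCorrectNormalize(c(a = 10, b = 80), c(ca = 20, cb = 20),
                                   data.frame(template = c("a", "b"),
                                              control = c("ca", "cb")))
  expect_equal(fl$corrected[1], 0)
  # adding a constant to all templates and controls leaves corrected unchanged
  sh <- backgroundCorrectNormalize(c(a = 600, b = 580), c(ca = 520, cb = 520),
                                   data.frame(template = c("a", "b"),
                                              control = c("ca", "cb")))
  expect_equal(sh$corrected, out$corrected)
  # degenerate: everything at or below control
  expect_error(backgroundCorrectNormalize(c(a = 5), c(ca = 9),
                                          data.frame(template = "a",
                                                     control = "ca")),
               "degenerate")
})

test_that("normalization is idempotent", {
  x <- c(0.2, 1.0, 0.5)
  again <- backgroundCorrectNormalize(x, rep(0, 3))
  expect_equal(again$normalized, x)
})

test_that("conversion efficiency: ratio arithmetic and undefined denominators", {
  rna <- aggregateScan(mkScan(rep(20, 10), probe = "r"))
  dna <- aggregateScan(mkScan(rep(100, 10), probe = "d"))
  eff <- conversionEfficiency(rna, dna, data.frame(rna = "r", dna = "d"),
                              nBoot = 50)
  expect_equal(eff$pairs$estimate, 20)
  expect_equal(eff$summary$efficiency, 20)
  # identical tables: 100% for every pair
  same <- conversionEfficiency(dna, dna, data.frame(rna = "d", dna = "d"),
                               nBoot = 50)
  expect_equal(same$summary$efficiency, 100)
  zero <- aggregateScan(mkScan(rep(0, 5), probe = "z"))
  expect_error(conversionEfficiency(rna, zero, data.frame(rna = "r", dna = "z"),
                                    nBoot = 10),
               "denominator mean <= 0")
})

test_that("simulated conversion efficiency is recovered within the bootstrap CI", {
  hits <- 0L
  for (s in 1:20) {
    est <- estimateEfficiency(e = 0.2, replicates = 24, seed = 100 + s,
                              nBoot = 200)
    if (est$summary$lo <= 20 && 20 <= est$summary$hi) hits <- hits + 1L
  }
  expect_gte(hits, 17)  # 95% CIs; allow the expected few misses
})

test_that("degradation residuals recover treated/buffer ratios", {
  tr <- aggregateScan(mkScan(rep(25, 8), probe = "x"))
  bu <- aggregateScan(mkScan(rep(100, 8), probe = "x"))
  res <- degradationResidual(tr, bu, data.frame(treated = "x", buffer = "x"),
                             nBoot = 50)
  expect_equal(res$summary$residual, 0.25)
  # buffer arm reused as treated arm: residual 1
  res1 <- degradationResidual(bu, bu, data.frame(treated = "x", buffer = "x"),
                              nBoot = 50)
  expect_equal(res1$summary$residual, 1.0)
  # simulated arms at the published scales: ~0.5 at 2 h, ~0.22 at 6 h
  design <- designTable(list(makeTemplate("TCAACCCAGGTCCAATTTCC", 5,
                                          probeId = "t")))
  layout <- replicateLayout(design, 24, nCols = 24, seed = 21)
  for (r in c(0.5, 0.22)) {
    p <- simParams(cv = 0.2, background = 0, seed = 23)
    scans <- simulateScan(layout, design, p,
                          list(armDegradation("treated", r = r),
                               armDegradation("buffer", r = 1)))
    est <- degradationResidual(aggregateScan(scans$treated),
                               aggregateScan(scans$buffer),
                               data.frame(treated = "t", buffer = "t"),
                               nBoot = 400, seed = 29)
    expect_true(est$summary$lo <= r && r <= est$summary$hi,
                label = sprintf("residual %g in CI [%g, %g]", r,
                                est$summary$lo, est$summary$hi))
  }
})

test_that("positional profile: exact plateau noise-free, flat when decay is off", {
  fx <- walkScan(cv = 0, seed = 41)
  pr <- positionalProfile(fx$scan, fx$design)
  expect_equal(pr$final20Mean, 0.70)
  expect_equal(pr$profile$relative[pr$profile$position == 1], 1.0)
  expect_equal(nrow(pr$profile), 21)
  # positions sampled every third nucleotide
  expect_equal(pr$profile$position, c(1, 3 * (1:20) + 1))
  # no decay: profile identically 1
  flat <- walkScan(cv = 0, seed = 42, decay = 1, plateau = 0.1)
  prF <- positionalProfile(flat$scan, flat$design)
  expect_true(all(prF$profile$relative == 1.0))
})

test_that("noisy positional profile recovers the plateau within 3 SE (85 replicates)", {
  fx <- walkScan(cv = 0.2, seed = 11, replicates = 85)
  pr <- positionalProfile(fx$scan, fx$design)
  # bootstrap the replicate features to estimate the SE of the plateau mean
  d <- scanData(fx$scan)
  groups <- split(seq_len(nrow(d)), d$probe_id)
  set.seed(43)
  boots <- replicate(200, {
    idx <- unlist(lapply(groups, function(ii) sample(ii, replace = TRUE)))
    positionalProfile(scanTable(d[idx, ], "boot"), fx$design)$final20Mean
  })
  expect_lt(abs(pr$final20Mean - 0.70), 3 * sd(boots))
})

test_that("positional profile needs the position-1 reference", {
  fx <- walkScan(cv = 0, seed = 47)
  d <- scanData(fx$scan)
  noRef <- scanTable(d[!d$probe_id %in% c("walk_00", "walkctrl_00"), ],
                     "partial")
  expect_error(positionalProfile(noRef, fx$design), "missing dA-walk probes")
})

test_that("efficiency estimator error shrinks with replicate count", {
  errAt <- function(n, seeds) {
    mean(vapply(seeds, function(s)
      abs(estimateEfficiency(0.2, n, seed = 200 + s, nBoot = 50)$summary$efficiency - 20),
      numeric(1)))
  }
  seeds <- 1:6
  errs <- vapply(c(8, 85), errAt, numeric(1), seeds = seeds)
  expect_lt(errs[2], errs[1])
  # at every published replicate count the estimate stays near truth
  for (n in c(8, 24, 62, 85)) {
    est <- estimateEfficiency(0.2, n, seed = 300 + n, nBoot = 50)
    expect_lt(abs(est$summary$efficiency - 20), 20 * 5 * 0.2 / sqrt(n))
  }
})

test_that("the simulate -> quantify pipeline is byte-stable given seeds", {
  run <- function() {
    fx <- walkScan(cv = 0.2, seed = 31, replicates = 8)
    positionalProfile(fx$scan, fx$design)
  }
  expect_identical(run(), run())
})
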