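# Independent oracles and small fixture builders shared across tests.

# Reverse complement oracle via an explicit per-base complement table,
# applied base by base in reverse -- independent of revComp()'s chartr path.
oracleRevComp <- function(seq, outChem = "DNA") {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  chars <- rev(strsplit(seq, "")[[1]])
  out <- unname(comp[chars])
  if (outChem != "DNA") out[out == "T"] <- "U"
  paste(out, collapse = "")
}

randomDNA <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Exhaustive subset-search oracle for level selection: enumerates all
# C(n, k) subsets in lexicographic order and scores sorted lengths against
# evenly spaced intensity targets; first argmin = lexicographically
# smallest tie-break.
oracleSelectLevels <- function(curve, k) {
  ord <- order(curve$length)
  len <- curve$length[ord]; intens <- curve$intensity[ord]
  targets <- seq(min(intens), max(intens), length.out = k)
  combos <- utils::combn(length(len), k)
  sse <- colSums((matrix(intens[combos], nrow = k) - targets)^2)
  as.integer(len[combos[, which.min(sse)]])
}

randomMonotoneCurve <- function(n) {
  data.frame(length = sort(sample(1:(3 * n), n)),
             intensity = cumsum(runif(n, 0.1, 5)))
}

# Minimal raw design table for lithography tests (bypasses makeTemplate
# so arbitrary short sequences can be scheduled).
rawDesign <- function(ids, fullSeqs, linkerLens = 0L) {
  designTable(data.frame(
    probe_id = ids, role = "transcribable",
    linker_len = rep_len(as.integer(linkerLens), length(ids)),
    variable = fullSeqs, full_sequence = fullSeqs,
    primer_name = NA_character_, ru_position = NA_real_,
    stringsAsFactors = FALSE))
}

gridLayout <- function(ids, nRows, nCols) {
  n <- length(ids)
  arrayLayout(nRows, nCols,
              data.frame(row = (seq_len(n) - 1L) %/% nCols,
                         col = (seq_len(n) - 1L) %% nCols,
                         probe_id = ids, stringsAsFactors = FALSE))
}

# Small RGB encoding (16 x 12 source, 2x2 block and tiling -> 48 x 64 grid)
smallRGBEncoding <- function(seed = 1, h = 12, w = 16) {
  set.seed(seed)
  img <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
  lv <- quantizeRGB(img, 8)
  maps <- lapply(channelTemplates(), function(s)
    selectLevels(syntheticCalibration(nchar(s)), 8))
  encodeImage(lv, maps)
}

# dA-walk simulation fixture
walkScan <- function(cv, seed, replicates = 85, decay = 0.96,
                     plateau = 0.70) {
  design <- daWalkSeries()
  layout <- replicateLayout(design, replicates, nCols = 60, seed = seed)
  params <- simParams(cv = cv, decay = decay, plateau = plateau, seed = seed)
  scan <- simulateScan(layout, design, params, list(armCy3Walk()))$cy3walk
  list(design = design, layout = layout, scan = scan)
}

# Conversion-efficiency simulation fixture: converted + untreated arms of
# a linker series design; returns the background-corrected estimator input.
efficiencyFixture <- function(e, replicates, seed, cv = 0.2) {
  ag <- agilentSeries(replicateCount = replicates, seed = seed)
  params <- simParams(cv = cv, efficiency = e, seed = seed)
  scans <- simulateScan(ag$layout, ag$design, params,
                        list(armConvertedRNA(e = e), armUntreatedDNA()))
  stConv <- aggregateScan(scans$converted, ag$design)
  stRef <- aggregateScan(scans$untreated, ag$design)
  tl <- templates(ag$design)
  refIds <- tl$probe_id[grepl("^ref_", tl$probe_id)]
  ctlIds <- sub("^ref_", "ctrl_", refIds)
  list(stConv = stConv, stRef = stRef,
       pairing = data.frame(rna = refIds, dna = ctlIds,
                            stringsAsFactors = FALSE),
       bgConv = mean(unlist(stConv$values[match(ctlIds, stConv$probe_id)])),
       bgRef = mean(unlist(stRef$values[match(refIds, stRef$probe_id)])))
}

estimateEfficiency <- function(e, replicates, seed, cv = 0.2, nBoot = 400) {
  fx <- efficiencyFixture(e, replicates, seed, cv)
  conversionEfficiency(fx$stConv, fx$stRef, fx$pairing,
                       rnaBackground = fx$bgConv, dnaBackground = fx$bgRef,
                       nBoot = nBoot, seed = seed)
}
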