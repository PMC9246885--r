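test_that("makeTemplate appends the shared primer-complement block and linker", {
  tpl <- makeTemplate("TCAACCCAGGTCCAATTTCC", 5, defaultPrimer())
  expect_identical(oligoSequence(tpl),
                   "TCAACCCAGGTCCAATTTCCTTCGCCGTGTCCCTATTTTT")
  expect_equal(nchar(oligoSequence(tpl)), 40)
  tplR <- makeTemplate("TCACCGAATCGATTCCATCTGCTTC", 5, defaultPrimer())
  expect_equal(nchar(oligoSequence(tplR)), 45)  # 25 + 15 + 5
  # 131 nt variable + 15 block + 5 linker = 151 > 150 ink-jet limit
  v131 <- randomDNA(1, 131)
  expect_error(makeTemplate(v131, 5, defaultPrimer()), "151.*150|150.*151")
  # the same probe is fine on the photolithography platform
  expect_s4_class(makeTemplate(v131, 5, defaultPrimer(),
                               platform = "photolithography"),
                  "TemplateSpec")
  expect_error(makeTemplate("", 5), "non-empty")
})

test_that("makeControl carries the product sequence as DNA without the primer site", {
  ctl <- makeControl("TCAACCCAGGTCCAATTTCC", 5)
  expect_identical(oligoSequence(ctl), paste0("GGAAATTGGACCTGGGTTGA", "TTTTT"))
  expect_identical(ctl@role, "control")
  # controls never share the primer-complement 15-mer with templates
  block <- revComp(oligoSequence(defaultPrimer()), "OMe", "DNA")
  tpl <- makeTemplate("TCAACCCAGGTCCAATTTCC", 5)
  expect_true(grepl(block, oligoSequence(tpl), fixed = TRUE))
  expect_false(grepl(block, oligoSequence(ctl), fixed = TRUE))
  # construction refuses a control that would contain the block
  expect_error(makeControl(paste0("AA", revComp(block, "DNA"), "CC"), 5),
               "primer-complement block")
})

test_that("crosslink-site validation checks duplex, terminal TA/UA pair and linker", {
  tpl <- makeTemplate("TCAACCCAGGTCCAATTTCC", 5, defaultPrimer())
  rep <- validateCrosslinkSite(tpl, defaultPrimer())
  expect_true(rep$pass)
  expect_equal(rep$duplexLen, 15)
  expect_length(rep$mismatches, 0)
  # primer with its 5' U changed to C: no T/A pair next to the psoralen
  mut <- primerSpec("CAGGGACACGGCGAA", "mut5")
  repMut <- validateCrosslinkSite(tpl, mut)
  expect_false(repMut$terminalPairIsUAorTA)
  expect_false(repMut$pass)
  # no linker: nothing 3' of the block to crosslink against
  tpl0 <- makeTemplate("TCAACCCAGGTCCAATTTCC", 0, defaultPrimer())
  rep0 <- validateCrosslinkSite(tpl0, defaultPrimer())
  expect_false(rep0$linkerFirstBaseIsT)
  expect_false(rep0$pass)
})

test_that("selectivity screen flags long unintended primer-complement stretches", {
  # plant 12 nt of the primer-complement block inside a variable region
  planted <- paste0("AAAA", "TTCGCCGTGTCC", "AAAA")
  lib <- designTable(list(
    makeTemplate(planted, 5, probeId = "planted"),
    makeTemplate("TCAACCCAGGTCCAATTTCC", 5, probeId = "clean")))
  hits <- primerSelectivityScreen(lib, defaultPrimer(), minFlagLen = 12)
  expect_equal(hits$probe_id, "planted")
  expect_equal(hits$stretch, 12)
  # the three channel variable regions are clean at the 12 nt threshold
  rgb <- designTable(lapply(names(channelTemplates()), function(ch)
    makeTemplate(channelTemplates()[[ch]], 5, probeId = ch)))
  expect_equal(nrow(primerSelectivityScreen(rgb, defaultPrimer(), 12)), 0)
  # degenerate threshold: any complementary base flags every template
  expect_equal(sort(primerSelectivityScreen(rgb, defaultPrimer(), 1)$probe_id),
               sort(names(channelTemplates())))
  # empty library
  empty <- designTable(list())
  expect_equal(nrow(primerSelectivityScreen(empty, defaultPrimer())), 0)
})

test_that("selectivity screen agrees with a brute-force all-substring oracle", {
  set.seed(31)
  primer <- defaultPrimer()
  pseq <- oligoSequence(primer)
  plen <- nchar(pseq)
  bruteLongest <- function(v) {
    best <- 0L
    for (len in 1:plen) for (s in 1:(plen - len + 1)) {
      sub <- chemConvert(substr(pseq, s, s + len - 1), "OMe", "DNA")
      if (grepl(oracleRevComp(sub), v, fixed = TRUE) ||
          grepl(sub, v, fixed = TRUE)) best <- max(best, len)
    }
    best
  }
  for (v in randomDNA(20, 30)) {
    lib <- designTable(list(makeTemplate(v, 5, probeId = "p")))
    hits <- primerSelectivityScreen(lib, primer, minFlagLen = 1)
    got <- if (nrow(hits) == 0) 0L else hits$stretch
    expect_equal(got, bruteLongest(v))
  }
})

test_that("distinctRearrangements enumerates multiset permutations", {
  expect_setequal(distinctRearrangements("CTA"),
                  c("CTA", "CAT", "TCA", "TAC", "ACT", "ATC"))
  expect_identical(distinctRearrangements("TTT"), "TTT")
  expect_length(distinctRearrangements("GGT"), 3)
})

test_that("the linker/permutation series has the published structure", {
  ag <- agilentSeries(replicateCount = 60, seed = 1)
  tl <- templates(ag$design)
  expect_equal(max(tl$linker_len), 20)
  expect_setequal(unique(tl$linker_len), c(5, 10, 15, 20))
  expect_true(all(nchar(tl$full_sequence) <= 150))
  expect_equal(replicateCount(ag$design), 60)
  # every probe placed exactly 60 times at randomized positions
  counts <- table(layoutFeatures(ag$layout)$probe_id)
  expect_true(all(counts == 60))
  expect_setequal(names(counts), tl$probe_id)
  # reference and central-mismatch templates keep a valid crosslink site
  for (id in tl$probe_id[grepl("^(ref|cperm)_", tl$probe_id)]) {
    row <- tl[tl$probe_id == id, ]
    tpl <- new("TemplateSpec", probeId = row$probe_id, variable = row$variable,
               primerName = row$primer_name, linkerLen = as.integer(row$linker_len),
               role = row$role, fullSequence = row$full_sequence,
               ruPosition = NA_real_)
    expect_true(validateCrosslinkSite(tpl, defaultPrimer())$pass, label = id)
  }
  # primer-site permutation variants break the terminal pairing on purpose
  pperm <- tl[grepl("^pperm_", tl$probe_id), ]
  expect_true(nrow(pperm) > 0)
  # duplicate probe ids are a construction error
  dup <- makeTemplate("ACGTACGT", 5, probeId = "dup")
  expect_error(designTable(list(dup, dup)), "duplicate probe_id")
})

test_that("dA-walk series: 61 nt single-A variable regions at every third position", {
  dw <- daWalkSeries()
  tl <- templates(dw)
  tpl <- tl[tl$role == "transcribable", ]
  ctl <- tl[tl$role == "control", ]
  expect_equal(nrow(tpl), 21)
  expect_equal(nrow(ctl), 21)
  expect_true(all(nchar(tpl$variable) == 61))
  # 20 after-a-dC insertion variants plus the surface-proximal variant 0
  expect_equal(sum(grepl("^walk_", tpl$probe_id) &
                   tpl$probe_id != "walk_00"), 20)
  for (i in seq_len(nrow(tpl))) {
    comp <- table(strsplit(tpl$variable[i], "")[[1]])
    expect_equal(as.integer(comp[c("A", "C", "G", "T")]), c(1L, 20L, 20L, 20L),
                 label = tpl$probe_id[i])
  }
  expect_setequal(tpl$ru_position, c(1, 3 * (1:20) + 1))
})

test_that("dA-walk rU positions match brute-force simulation of templated extension", {
  dw <- daWalkSeries()
  tl <- templates(dw)
  tpl <- tl[tl$role == "transcribable", ]
  for (i in seq_len(nrow(tpl))) {
    # extension proceeds along the template 3'->5': product base j pairs the
    # variable-region base j counted from its 3' (surface-proximal) end
    tchars <- rev(strsplit(tpl$variable[i], "")[[1]])
    product <- chartr("ACGT", "UGCA", paste(tchars, collapse = ""))
    expect_equal(unname(regexpr("U", product)[1]), tpl$ru_position[i],
                 label = tpl$probe_id[i])
  }
  expect_equal(tpl$ru_position[tpl$probe_id == "walk_00"], 1)
  # the variant with its dA at the distal (5') end of the variable region
  distal <- tpl[substr(tpl$variable, 1, 1) == "A", ]
  expect_equal(nrow(distal), 1)
  expect_equal(distal$ru_position, 61)
})

test_that("template -> product -> complement round trip recovers the variable region", {
  set.seed(17)
  for (v in randomDNA(1000, 25)) {
    tpl <- makeTemplate(v, 5, defaultPrimer())
    rna <- oligoSegments(predictedProduct(tpl, defaultPrimer()))$seq[2]
    expect_identical(revComp(rna, "RNA", "DNA"), v)
  }
})
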