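# Construction and validation of convertible template libraries.

PLATFORM_LIMITS <- c(inkjet = 150L, photolithography = NA_integer_)

.platformLimit <- function(platform) {
  if (!platform %in% names(PLATFORM_LIMITS))
    stop(sprintf("unknown platform '%s'", platform))
  PLATFORM_LIMITS[[platform]]
}

.checkPlatform <- function(fullLen, platform, probeId = "?") {
  lim <- .platformLimit(platform)
  if (!is.na(lim) && fullLen > lim)
    stop(sprintf("probe '%s': full sequence length %d exceeds the %d nt %s platform limit",
                 probeId, fullLen, lim, platform))
  invisible(fullLen)
}

#' Construct a transcribable template probe
#'
#' Full sequence 5'->3' = variable region + reverse complement of the
#' primer (the primer hybridization / crosslinking site) + dT linker to
#' the surface.
#'
#' @param variable variable (template) region, DNA 5'->3', non-empty.
#' @param linkerLen dT homopolymer linker length (nt), >= 0.
#' @param primer a [PrimerSpec-class].
#' @param probeId identifier.
#' @param platform `"inkjet"` (150 nt length limit) or
#'   `"photolithography"` (no sequence-length limit).
#' @return A transcribable [TemplateSpec-class].
#' @examples
#' makeTemplate("TCAACCCAGGTCCAATTTCC", 5, defaultPrimer())
#' @export
makeTemplate <- function(variable, linkerLen = 5L, primer = defaultPrimer(),
                         probeId = "template", platform = "inkjet") {
  if (length(variable) != 1 || nchar(variable) == 0)
    stop("makeTemplate: variable region must be a non-empty DNA string")
  msg <- .checkAlphabet(variable, "DNA")
  if (!is.null(msg)) stop("makeTemplate: ", msg)
  if (linkerLen < 0) stop("makeTemplate: linkerLen must be >= 0")
  full <- paste0(variable, revComp(oligoSequence(primer), "OMe", "DNA"),
                 strrep("T", linkerLen))
  .checkPlatform(nchar(full), platform, probeId)
  new("TemplateSpec", probeId = probeId, variable = variable,
      primerName = primer@name, linkerLen = as.integer(linkerLen),
      role = "transcribable", fullSequence = full, ruPosition = NA_real_)
}

#' Construct an untranscribable control probe
#'
#' Controls lack the primer-complement block and carry the RNA product
#' sequence as DNA (`revcomp(variable)`), so the same labelled detection
#' probe hybridizes directly; they serve as synthesis-quality checks and
#' as ssDNA intensity references. Construction asserts that the control
#' shares no primer-complement stretch with the corresponding template.
#'
#' @inheritParams makeTemplate
#' @param primer primer the companion template was designed against; used
#'   only for the shared-block assertion.
#' @return A control [TemplateSpec-class].
#' @examples
#' makeControl("TCAACCCAGGTCCAATTTCC", 5)
#' @export
makeControl <- function(variable, linkerLen = 5L, primer = defaultPrimer(),
                        probeId = "control", platform = "inkjet") {
  if (length(variable) != 1 || nchar(variable) == 0)
    stop("makeControl: variable region must be a non-empty DNA string")
  msg <- .checkAlphabet(variable, "DNA")
  if (!is.null(msg)) stop("makeControl: ", msg)
  if (linkerLen < 0) stop("makeControl: linkerLen must be >= 0")
  full <- paste0(revComp(variable, "DNA"), strrep("T", linkerLen))
  .checkPlatform(nchar(full), platform, probeId)
  block <- revComp(oligoSequence(primer), "OMe", "DNA")
  if (grepl(block, full, fixed = TRUE))
    stop(sprintf("makeControl: probe '%s' contains the primer-complement block %s; it would be transcribable",
                 probeId, block))
  new("TemplateSpec", probeId = probeId, variable = variable,
      primerName = NA_character_, linkerLen = as.integer(linkerLen),
      role = "control", fullSequence = full, ruPosition = NA_real_)
}

#' Validate the psoralen crosslink site of a template
#'
#' Psoralen intercalates at the duplex end next to the primer's 5'
#' terminus and needs a T/A (or U/A) base pair there to crosslink. The
#' report checks that (i) the primer forms a full-length Watson-Crick
#' duplex with the template's primer-complement block (U:A allowed),
#' (ii) the terminal pair adjacent to the psoralen is U:A or T:A, and
#' (iii) the first linker base 3' of the block is a T.
#'
#' @param template a transcribable [TemplateSpec-class].
#' @param primer a [PrimerSpec-class].
#' @return A list: `duplexLen`, `allWatsonCrick`, `terminalPairIsUAorTA`,
#'   `linkerFirstBaseIsT`, `pass` (conjunction), `mismatches` (duplex
#'   positions failing Watson-Crick pairing, 1 = primer 5' end).
#' @examples
#' validateCrosslinkSite(makeTemplate("TCAACCCAGGTCCAATTTCC", 5), defaultPrimer())
#' @export
validateCrosslinkSite <- function(template, primer = defaultPrimer()) {
  stopifnot(is(template, "TemplateSpec"), is(primer, "PrimerSpec"))
  if (template@role != "transcribable")
    stop("validateCrosslinkSite: only transcribable templates carry a crosslink site")
  pseq <- strsplit(oligoSequence(primer), "")[[1]]
  plen <- length(pseq)
  full <- template@fullSequence
  vlen <- nchar(template@variable)
  block <- strsplit(substr(full, vlen + 1, vlen + plen), "")[[1]]
  if (length(block) < plen)
    stop("validateCrosslinkSite: template shorter than variable + primer length")
  # primer base i (from its 5' end) pairs the block base plen - i + 1
  partner <- rev(block)
  wc <- .isWCPair(pseq, partner)
  mism <- which(!wc)
  terminal <- length(mism) == 0 || !(1 %in% mism)
  terminalUA <- .isWCPair(pseq[1], partner[1]) &&
    chartr("U", "T", pseq[1]) %in% c("T", "A")
  linkerBase <- substr(full, vlen + plen + 1, vlen + plen + 1)
  linkerT <- identical(linkerBase, "T")
  res <- list(duplexLen = plen,
              allWatsonCrick = length(mism) == 0,
              terminalPairIsUAorTA = terminalUA,
              linkerFirstBaseIsT = linkerT,
              mismatches = mism)
  res$pass <- res$allWatsonCrick && res$terminalPairIsUAorTA &&
    res$linkerFirstBaseIsT
  res
}

#' Screen a library for unintended primer-binding sites
#'
#' For each transcribable template, finds the longest contiguous stretch
#' of the primer whose complement occurs inside the variable region (on
#' either strand); the intended primer-complement block is outside the
#' variable region and therefore excluded by construction. Templates
#' whose longest stretch reaches `minFlagLen` are reported: with fewer
#' than 12 complementary nt the primer cannot stably mis-hybridize, which
#' is why 12 nt is both the default flag threshold and the primer-length
#' floor.
#'
#' @param design a [DesignTable-class].
#' @param primer a [PrimerSpec-class].
#' @param minFlagLen minimum stretch length to flag (>= 1).
#' @return data.frame of hits: `probe_id`, `stretch` (nt),
#'   `primer_offset` (1-based start in the primer), `variable_offset`
#'   (1-based start of the complementary match in the variable region),
#'   `strand` (`"+"` the complement occurs as written, `"-"` on the
#'   reverse strand). Empty data.frame when nothing is flagged.
#' @export
primerSelectivityScreen <- function(design, primer = defaultPrimer(),
                                    minFlagLen = 12L) {
  stopifnot(is(design, "DesignTable"))
  if (minFlagLen < 1) stop("primerSelectivityScreen: minFlagLen must be >= 1")
  pseq <- oligoSequence(primer)
  plen <- nchar(pseq)
  tl <- templates(design)
  tl <- tl[tl$role == "transcribable", , drop = FALSE]
  hits <- list()
  for (r in seq_len(nrow(tl))) {
    v <- tl$variable[r]
    if (nchar(v) == 0) next
    found <- NULL
    for (len in seq(plen, 1)) {
      for (s in seq_len(plen - len + 1)) {
        sub <- substr(pseq, s, s + len - 1)
        subDNA <- chemConvert(sub, "OMe", "DNA")
        # complement of the primer stretch on the written strand of v:
        m <- regexpr(revComp(subDNA, "DNA"), v, fixed = TRUE)
        if (m > 0) {
          found <- data.frame(probe_id = tl$probe_id[r], stretch = len,
                              primer_offset = s, variable_offset = as.integer(m),
                              strand = "+", stringsAsFactors = FALSE)
          break
        }
        # ... or on the reverse strand (the primer stretch itself appears in v)
        m <- regexpr(subDNA, v, fixed = TRUE)
        if (m > 0) {
          found <- data.frame(probe_id = tl$probe_id[r], stretch = len,
                              primer_offset = s, variable_offset = as.integer(m),
                              strand = "-", stringsAsFactors = FALSE)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found) && found$stretch >= minFlagLen)
      hits[[length(hits) + 1]] <- found
  }
  if (length(hits) == 0)
    return(data.frame(probe_id = character(), stretch = integer(),
                      primer_offset = integer(), variable_offset = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' All distinct rearrangements of the characters of a string
#'
#' Multiset permutations, deduplicated; e.g. `"TTT"` has exactly one.
#'
#' @param x a single string.
#' @return Character vector of distinct rearrangements (includes `x`).
#' @examples
#' distinctRearrangements("CTA")  # 6 orderings
#' distinctRearrangements("TTT")  # 1
#' @export
distinctRearrangements <- function(x) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  if (n == 0) return(character(0))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  unique(vapply(perms(chars), paste, character(1), collapse = ""))
}

#' Linker / permutation variant series for an ink-jet design
#'
#' Emits, for each linker length (dTn, n = 5, 10, 15, 20 by default): the
#' reference template; every non-identity distinct rearrangement of the 3
#' bases at the 3' terminus of the primer-complement block; every
#' non-identity distinct rearrangement of the 3 centermost variable-region
#' bases (mismatch series); the untranscribable control; and a P-tc
#' reference probe (primer sequence as DNA + product sequence as DNA) for
#' direct hybridization of the labelled detection oligo. Each probe is
#' placed `replicateCount` times at seeded random positions.
#'
#' @param baseVariable reference variable region, DNA 5'->3', >= 7 nt.
#' @param primer a [PrimerSpec-class].
#' @param linkerLens dT linker lengths to emit.
#' @param replicateCount replicates of every probe (60 in the published
#'   design).
#' @param seed placement randomization seed.
#' @param platform length-limit platform, see [makeTemplate()].
#' @return list with `design` (a [DesignTable-class]) and `layout` (an
#'   [ArrayLayout-class] with randomized replicate positions).
#' @export
agilentSeries <- function(baseVariable = "TCAACCCAGGTCCAATTTCC",
                          primer = defaultPrimer(),
                          linkerLens = c(5L, 10L, 15L, 20L),
                          replicateCount = 60L, seed = 1L,
                          platform = "inkjet") {
  if (nchar(baseVariable) < 7)
    stop("agilentSeries: baseVariable must be >= 7 nt (needs 3 central positions)")
  block <- revComp(oligoSequence(primer), "OMe", "DNA")
  blen <- nchar(block)
  term3 <- substr(block, blen - 2, blen)
  L <- nchar(baseVariable)
  centerIdx <- (L %/% 2):(L %/% 2 + 2)        # 1-based; 0-based floor(L/2)-1 .. +1
  center <- paste(strsplit(baseVariable, "")[[1]][centerIdx], collapse = "")
  specs <- list()
  add <- function(s) specs[[length(specs) + 1]] <<- s
  for (n in linkerLens) {
    tag <- sprintf("dT%02d", n)
    add(makeTemplate(baseVariable, n, primer, sprintf("ref_%s", tag), platform))
    for (p in setdiff(distinctRearrangements(term3), term3)) {
      full <- paste0(baseVariable, substr(block, 1, blen - 3), p, strrep("T", n))
      .checkPlatform(nchar(full), platform, sprintf("pperm_%s_%s", p, tag))
      add(new("TemplateSpec", probeId = sprintf("pperm_%s_%s", p, tag),
              variable = baseVariable, primerName = primer@name,
              linkerLen = as.integer(n), role = "transcribable",
              fullSequence = full, ruPosition = NA_real_))
    }
    for (p in setdiff(distinctRearrangements(center), center)) {
      vchars <- strsplit(baseVariable, "")[[1]]
      vchars[centerIdx] <- strsplit(p, "")[[1]]
      v <- paste(vchars, collapse = "")
      add(makeTemplate(v, n, primer, sprintf("cperm_%s_%s", p, tag), platform))
    }
    add(makeControl(baseVariable, n, primer, sprintf("ctrl_%s", tag), platform))
    ptc <- paste0(chemConvert(oligoSequence(primer), "OMe", "DNA"),
                  revComp(baseVariable, "DNA"), strrep("T", n))
    .checkPlatform(nchar(ptc), platform, sprintf("ptc_%s", tag))
    add(new("TemplateSpec", probeId = sprintf("ptc_%s", tag),
            variable = baseVariable, primerName = NA_character_,
            linkerLen = as.integer(n), role = "control",
            fullSequence = ptc, ruPosition = NA_real_))
  }
  design <- designTable(specs, replicateCount = replicateCount,
                        metadata = list(platform = platform,
                                        primer = primer@name,
                                        seed = as.integer(seed),
                                        base_variable = baseVariable))
  layout <- replicateLayout(design, replicateCount = replicateCount, seed = seed)
  list(design = design, layout = layout)
}

#' dA-walk template series for positional incorporation profiling
#'
#' 21 transcribable templates whose 61 nt variable region is a 20-fold
#' TGC concatemer (counted surface-proximal to distal) carrying exactly
#' one dA: variant 0 places it adjacent to the primer-complement block,
#' variants 1..20 immediately after the k-th dC of the concatemer. A
#' single Cy3-rU is therefore templated at extension position
#' `3k + 1` (1 = surface-proximal), sampling every third position of the
#' 61 nt extension; matched no-primer-complement controls account for
#' nonspecific Cy3-UTP surface binding. Composition of every variable
#' region is A:1, T:20, G:20, C:20.
#'
#' @param linkerLen dT linker length.
#' @param primer a [PrimerSpec-class].
#' @param replicateCount intended replicates (85 in the published assay).
#' @return A [DesignTable-class] of 21 templates (`walk_00` .. `walk_20`)
#'   and 21 controls (`walkctrl_*`), each annotated with `ru_position`.
#' @export
daWalkSeries <- function(linkerLen = 5L, primer = defaultPrimer(),
                         replicateCount = 85L) {
  concat <- strrep("TGC", 20)  # written surface-proximal -> distal (3'->5')
  specs <- list()
  for (k in 0:20) {
    s35 <- if (k == 0) paste0("A", concat)
           else paste0(substr(concat, 1, 3 * k), "A",
                       substr(concat, 3 * k + 1, 60))
    variable <- .revString(s35)  # 5'->3'
    ruPos <- if (k == 0) 1 else 3 * k + 1
    tpl <- makeTemplate(variable, linkerLen, primer,
                        sprintf("walk_%02d", k), "photolithography")
    tpl@ruPosition <- as.numeric(ruPos)
    ctl <- makeControl(variable, linkerLen, primer,
                       sprintf("walkctrl_%02d", k), "photolithography")
    ctl@ruPosition <- as.numeric(ruPos)
    specs[[length(specs) + 1]] <- tpl
    specs[[length(specs) + 1]] <- ctl
  }
  designTable(specs, replicateCount = replicateCount,
              metadata = list(platform = "photolithography",
                              primer = primer@name, assay = "dA-walk"))
}

#' Randomized replicate placement of a design on a grid
#'
#' Places every probe of a design `replicateCount` times at randomized
#' grid positions (probe positions are randomized on the surface in the
#' published workflow). The grid defaults to the smallest `nCols`-wide
#' rectangle holding all replicates.
#'
#' @param design a [DesignTable-class].
#' @param replicateCount replicates per probe (defaults to the design's).
#' @param nCols grid width.
#' @param seed placement seed.
#' @return An [ArrayLayout-class].
#' @export
replicateLayout <- function(design, replicateCount = NULL, nCols = 64L,
                            seed = 1L) {
  stopifnot(is(design, "DesignTable"))
  if (is.null(replicateCount)) replicateCount <- replicateCount(design)
  ids <- rep(probeIds(design), each = replicateCount)
  n <- length(ids)
  nRows <- ceiling(n / nCols)
  set.seed(seed)
  cells <- sample.int(nRows * nCols, n)  # 0-based row-major index = cells - 1
  feat <- data.frame(row = (cells - 1L) %/% nCols,
                     col = (cells - 1L) %% nCols,
                     probe_id = ids, stringsAsFactors = FALSE)
  arrayLayout(nRows, nCols, feat)
}
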