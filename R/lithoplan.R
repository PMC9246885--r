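# Maskless photolithographic synthesis planning and replay verification.

# dose (J/cm2) and coupling time (s) per monomer class
.MONOMER_DOSE <- c(dA = 3.0, dC = 3.0, dG = 3.0, dT = 3.0,
                   HEG = 6.0, `dT-DMTr` = 0.0)
.MONOMER_TIME <- c(dA = 15, dC = 15, dG = 15, dT = 15,
                   HEG = 300, `dT-DMTr` = 120)

#' Schedule maskless synthesis of a layout
#'
#' Converts an array layout plus its design into an ordered cycle
#' schedule with per-cycle micromirror masks. Synthesis proceeds 3'->5'
#' (surface-proximal base first). Linker positions shared by every probe
#' (the minimum dT linker length across the design) are emitted first as
#' unmasked FLOOD couplings of acid-deprotected DMTr-dT; remaining
#' positions cycle through `baseOrder` with BzNPPOC-dN chemistry, the
#' mask of a base-b cycle switching on exactly the features whose next
#' unsynthesized (3'-most remaining) base is b. Cycles with all-off masks
#' are dropped.
#'
#' @param layout an [ArrayLayout-class].
#' @param design the companion [DesignTable-class] resolving every probe.
#' @param baseOrder cyclic coupling order (default `"ACGT"`).
#' @return A [SynthesisPlan-class].
#' @export
scheduleSynthesis <- function(layout, design, baseOrder = "ACGT") {
  stopifnot(is(layout, "ArrayLayout"), is(design, "DesignTable"))
  feat <- layoutFeatures(layout)
  tl <- templates(design)
  miss <- setdiff(feat$probe_id, tl$probe_id)
  if (length(miss) > 0)
    stop(sprintf("scheduleSynthesis: unresolved probe_id(s): %s",
                 paste(utils::head(miss, 3), collapse = ", ")))
  order_ <- strsplit(baseOrder, "")[[1]]
  if (anyDuplicated(order_)) stop("scheduleSynthesis: baseOrder must not repeat monomers")
  idx <- match(feat$probe_id, tl$probe_id)
  seqs <- tl$full_sequence[idx]
  nFeat <- nrow(feat)
  nR <- layout@nRows; nC <- layout@nCols
  cycles <- list(); masks <- list()
  floodLen <- if (nFeat > 0) min(tl$linker_len[idx]) else 0L
  if (nFeat > 0 && floodLen > 0) {
    tails <- substr(seqs, nchar(seqs) - floodLen + 1, nchar(seqs))
    stopifnot(all(tails == strrep("T", floodLen)))  # linkers are dT by construction
    for (i in seq_len(floodLen))
      cycles[[length(cycles) + 1]] <-
        data.frame(monomer = "dT-DMTr", mask = NA_character_,
                   dose = 0.0, coupling_time = 120, stringsAsFactors = FALSE)
  }
  rem <- substr(seqs, 1, nchar(seqs) - floodLen)
  chars <- lapply(strsplit(rem, ""), rev)  # synthesis order, 3' first
  bad <- setdiff(unique(unlist(chars)), order_)
  if (length(bad) > 0)
    stop(sprintf("scheduleSynthesis: monomer(s) %s absent from base order '%s'",
                 paste(bad, collapse = ", "), baseOrder))
  pos <- rep(1L, nFeat)
  lens <- lengths(chars)
  rowIdx <- feat$row + 1L; colIdx <- feat$col + 1L
  b <- 0L
  while (any(pos <= lens)) {
    b <- b %% length(order_) + 1L
    base <- order_[b]
    nxt <- vapply(seq_len(nFeat), function(i) {
      if (pos[i] <= lens[i]) chars[[i]][pos[i]] else NA_character_
    }, character(1))
    active <- !is.na(nxt) & nxt == base
    if (!any(active)) next
    m <- matrix(FALSE, nR, nC)
    m[cbind(rowIdx[active], colIdx[active])] <- TRUE
    maskId <- sprintf("mask_%04d", length(masks) + 1)
    masks[[maskId]] <- m
    cycles[[length(cycles) + 1]] <-
      data.frame(monomer = paste0("d", base), mask = maskId,
                 dose = 3.0, coupling_time = 15, stringsAsFactors = FALSE)
    pos[active] <- pos[active] + 1L
  }
  cy <- if (length(cycles) > 0) do.call(rbind, cycles)
        else data.frame(monomer = character(), mask = character(),
                        dose = numeric(), coupling_time = numeric(),
                        stringsAsFactors = FALSE)
  cy <- cbind(cycle = seq_len(nrow(cy)), cy)
  new("SynthesisPlan", cycles = cy, masks = masks,
      nRows = as.integer(nR), nCols = as.integer(nC))
}

#' Replay a synthesis plan
#'
#' Simulates the couplings mask by mask and reconstructs the sequence
#' grown at every feature; the independent verification oracle for
#' [scheduleSynthesis()].
#'
#' @param plan a [SynthesisPlan-class].
#' @param layout the [ArrayLayout-class] the plan was scheduled for.
#' @return Character vector of reconstructed 5'->3' sequences, one per
#'   feature row of the layout.
#' @export
replaySynthesis <- function(plan, layout) {
  stopifnot(is(plan, "SynthesisPlan"), is(layout, "ArrayLayout"))
  feat <- layoutFeatures(layout)
  nFeat <- nrow(feat)
  if (nFeat == 0) return(character(0))
  rowIdx <- feat$row + 1L; colIdx <- feat$col + 1L
  grown <- vector("list", nFeat)
  cy <- planCycles(plan)
  masks <- planMasks(plan)
  for (i in seq_len(nrow(cy))) {
    mono <- cy$monomer[i]
    base <- if (mono == "dT-DMTr") "T"
            else if (mono == "HEG") "h"
            else sub("^d", "", mono)
    if (is.na(cy$mask[i])) {
      active <- rep(TRUE, nFeat)
    } else {
      m <- masks[[cy$mask[i]]]
      active <- m[cbind(rowIdx, colIdx)]
    }
    w <- which(active)
    for (j in w) grown[[j]] <- c(grown[[j]], base)
  }
  vapply(grown, function(g) {
    if (is.null(g)) "" else paste(rev(g), collapse = "")
  }, character(1))
}

#' Dose and time budget of a synthesis plan
#'
#' @param plan a [SynthesisPlan-class].
#' @return list with `nCycles`, `totalDose` (J/cm2) and
#'   `totalCouplingTime` (s), summed with the per-monomer constants
#'   (BzNPPOC-dN 3 J/cm2 / 15 s, NPPOC-HEG 6 J/cm2 / 300 s, DMTr-dT
#'   0 J/cm2 / 120 s).
#' @export
synthesisStats <- function(plan) {
  cy <- planCycles(plan)
  list(nCycles = nrow(cy), totalDose = sum(cy$dose),
       totalCouplingTime = sum(cy$coupling_time))
}
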