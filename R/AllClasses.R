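#' @import methods
NULL

CHEMISTRIES <- c("DNA", "RNA", "OMe")
LABELS5 <- c("none", "psoralen", "Cy3", "Cy5", "FAM")
LABELS3 <- c("none", "surface")
ROLES <- c("transcribable", "control")

.alphabet <- function(chem) {
  if (chem == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
}

.checkAlphabet <- function(seq, chem) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .alphabet(chem))
  if (length(bad) > 0) {
    sprintf("invalid %s character '%s' at position %d", chem, chars[bad[1]], bad[1])
  } else {
    NULL
  }
}

#' Chimeric oligonucleotide
#'
#' A single nucleic acid strand modelled as an ordered run of segments, each
#' with its own sugar chemistry (DNA, RNA or 2'-O-methyl RNA), plus optional
#' terminal labels. All sequences are stored and displayed 5'->3'; surface
#' attachment is recorded as a 3' flag, never by reversing the string. The
#' species handled by the conversion workflow are block chimeras (e.g. a
#' 5'-psoralen 2'-OMe primer extended by an RNA segment), so chemistry is
#' per segment, never per base.
#'
#' @slot segments data.frame with columns `seq` (character, 5'->3') and
#'   `chem` (one of `"DNA"`, `"RNA"`, `"OMe"`).
#' @slot label5 one of `"none"`, `"psoralen"`, `"Cy3"`, `"Cy5"`, `"FAM"`.
#' @slot label3 one of `"none"`, `"surface"`.
#' @aliases ChimericOligo-class
#' @exportClass ChimericOligo
setClass("ChimericOligo",
  representation(segments = "data.frame", label5 = "character",
                 label3 = "character"),
  prototype(segments = data.frame(seq = character(), chem = character(),
                                  stringsAsFactors = FALSE),
            label5 = "none", label3 = "none"))

setValidity("ChimericOligo", function(object) {
  seg <- object@segments
  if (!all(c("seq", "chem") %in% names(seg)))
    return("segments must have columns 'seq' and 'chem'")
  if (nrow(seg) == 0) return("at least one segment is required")
  if (any(!seg$chem %in% CHEMISTRIES))
    return(sprintf("unknown chemistry: %s",
                   paste(setdiff(seg$chem, CHEMISTRIES), collapse = ", ")))
  if (any(nchar(seg$seq) == 0)) return("segments must be non-empty")
  for (i in seq_len(nrow(seg))) {
    msg <- .checkAlphabet(seg$seq[i], seg$chem[i])
    if (!is.null(msg)) return(sprintf("segment %d: %s", i, msg))
  }
  if (length(object@label5) != 1 || !object@label5 %in% LABELS5)
    return("label5 must be one of: " %+% paste(LABELS5, collapse = ", "))
  if (length(object@label3) != 1 || !object@label3 %in% LABELS3)
    return("label3 must be one of: " %+% paste(LABELS3, collapse = ", "))
  TRUE
})

`%+%` <- function(a, b) paste0(a, b)

#' Construct a ChimericOligo
#'
#' @param seqs character vector of segment sequences, 5'->3'.
#' @param chems character vector of per-segment chemistries
#'   (`"DNA"`, `"RNA"`, `"OMe"`), recycled to `length(seqs)`.
#' @param label5,label3 terminal labels.
#' @return A [ChimericOligo-class] object.
#' @examples
#' chimericOligo(c("UAGGGACACGGCGAA", "GGAAAUUGGACCUGGGUUGA"),
#'               c("OMe", "RNA"), label5 = "psoralen")
#' @export
chimericOligo <- function(seqs, chems, label5 = "none", label3 = "none") {
  chems <- rep_len(chems, length(seqs))
  new("ChimericOligo",
      segments = data.frame(seq = as.character(seqs), chem = as.character(chems),
                            stringsAsFactors = FALSE),
      label5 = label5, label3 = label3)
}

#' Universal conversion primer
#'
#' A 5'-psoralen 2'-O-methyl RNA primer. The psoralen intercalates at the
#' duplex terminus and photocrosslinks under 365 nm light, permanently
#' tethering the primer (and later the RNA extension product) to the
#' template strand. Primers shorter than 12 nt cannot maintain selectivity
#' on complex libraries, so the validity check enforces a 12 nt floor.
#'
#' @slot oligo a single-segment 2'-OMe [ChimericOligo-class] with
#'   `label5 = "psoralen"`.
#' @slot name identifier.
#' @aliases PrimerSpec-class
#' @exportClass PrimerSpec
setClass("PrimerSpec",
  representation(oligo = "ChimericOligo", name = "character"))

setValidity("PrimerSpec", function(object) {
  seg <- object@oligo@segments
  if (nrow(seg) != 1) return("primer must be a single segment")
  if (seg$chem != "OMe") return("primer chemistry must be 2'-OMe")
  if (object@oligo@label5 != "psoralen") return("primer must carry a 5' psoralen")
  if (nchar(seg$seq) < 12)
    return(sprintf("primer length %d < 12 nt selectivity floor", nchar(seg$seq)))
  if (length(object@name) != 1 || !nzchar(object@name))
    return("primer needs a non-empty name")
  TRUE
})

#' @param sequence 2'-OMe sequence 5'->3' (A/C/G/U), >= 12 nt.
#' @param name identifier.
#' @rdname PrimerSpec-class
#' @export
primerSpec <- function(sequence, name = "primer") {
  new("PrimerSpec",
      oligo = chimericOligo(sequence, "OMe", label5 = "psoralen"),
      name = name)
}

#' Default universal primer
#'
#' The 15 nt 5'-psoralen 2'-OMe primer `UAGGGACACGGCGAA` shared by all
#' convertible designs; its reverse complement plus a dT5 linker forms the
#' common `TTCGCCGTGTCCCTATTTTT` 3' block of every transcribable template.
#'
#' @return A [PrimerSpec-class].
#' @examples
#' defaultPrimer()
#' @export
defaultPrimer <- function() primerSpec("UAGGGACACGGCGAA", name = "Ps-OMe15")

#' Surface-bound template probe
#'
#' One DNA probe of a convertible microarray, written 5'->3' with the
#' surface attachment at the 3' end. Transcribable probes read
#' `variable + revcomp(primer) + dT linker`; untranscribable controls lack
#' the primer-complement block and instead carry the RNA product sequence
#' as DNA (`revcomp(variable) + dT linker`), so they hybridize the same
#' labelled detection probe without serving as polymerase templates.
#'
#' @slot probeId identifier, unique within a design.
#' @slot variable variable (template) region, DNA 5'->3'.
#' @slot primerName name of the primer the probe was designed against
#'   (`NA` for controls).
#' @slot linkerLen dT homopolymer linker length (nt).
#' @slot role `"transcribable"` or `"control"`.
#' @slot fullSequence complete probe sequence, DNA 5'->3'.
#' @slot ruPosition for dA-walk probes, the extension position (1-based,
#'   surface-proximal = 1) of the single templated rU; `NA` otherwise.
#' @aliases TemplateSpec-class
#' @exportClass TemplateSpec
setClass("TemplateSpec",
  representation(probeId = "character", variable = "character",
                 primerName = "character", linkerLen = "integer",
                 role = "character", fullSequence = "character",
                 ruPosition = "numeric"),
  prototype(ruPosition = NA_real_))

setValidity("TemplateSpec", function(object) {
  if (!object@role %in% ROLES)
    return("role must be 'transcribable' or 'control'")
  if (object@linkerLen < 0) return("linkerLen must be >= 0")
  msg <- .checkAlphabet(object@fullSequence, "DNA")
  if (!is.null(msg)) return(msg)
  if (nchar(object@variable) > 0) {
    msg <- .checkAlphabet(object@variable, "DNA")
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' Template design table
#'
#' A library of [TemplateSpec-class] probes held as one data.frame row per
#' probe, plus replicate bookkeeping and free-form metadata (platform,
#' primer, seed, ...). Probe identifiers are unique.
#'
#' @slot templates data.frame with columns `probe_id`, `role`,
#'   `linker_len`, `variable`, `full_sequence`, `primer_name`,
#'   `ru_position`.
#' @slot replicateCount intended replicates per probe on the array.
#' @slot metadata named list.
#' @aliases DesignTable-class
#' @exportClass DesignTable
setClass("DesignTable",
  representation(templates = "data.frame", replicateCount = "integer",
                 metadata = "list"),
  prototype(replicateCount = 1L, metadata = list()))

.DESIGN_COLS <- c("probe_id", "role", "linker_len", "variable",
                  "full_sequence", "primer_name", "ru_position")

setValidity("DesignTable", function(object) {
  tl <- object@templates
  if (!all(.DESIGN_COLS %in% names(tl)))
    return(sprintf("templates must have columns: %s",
                   paste(.DESIGN_COLS, collapse = ", ")))
  if (anyDuplicated(tl$probe_id))
    return(sprintf("duplicate probe_id: %s",
                   tl$probe_id[duplicated(tl$probe_id)][1]))
  if (object@replicateCount < 1L) return("replicateCount must be >= 1")
  if (nrow(tl) > 0 && any(!tl$role %in% ROLES)) return("unknown role in templates")
  TRUE
})

#' Build a DesignTable from TemplateSpec objects
#'
#' @param specs list of [TemplateSpec-class] objects (or a ready-made
#'   data.frame in the internal column layout).
#' @param replicateCount replicates per probe.
#' @param metadata named list of design metadata.
#' @return A [DesignTable-class].
#' @export
designTable <- function(specs, replicateCount = 1L, metadata = list()) {
  if (is.data.frame(specs)) {
    tl <- specs
  } else {
    tl <- do.call(rbind, lapply(specs, function(s) {
      data.frame(probe_id = s@probeId, role = s@role,
                 linker_len = s@linkerLen, variable = s@variable,
                 full_sequence = s@fullSequence, primer_name = s@primerName,
                 ru_position = s@ruPosition, stringsAsFactors = FALSE)
    }))
    if (is.null(tl))
      tl <- data.frame(probe_id = character(), role = character(),
                       linker_len = integer(), variable = character(),
                       full_sequence = character(), primer_name = character(),
                       ru_position = numeric(), stringsAsFactors = FALSE)
  }
  rownames(tl) <- NULL
  new("DesignTable", templates = tl,
      replicateCount = as.integer(replicateCount), metadata = metadata)
}

#' Rectangular array layout
#'
#' Maps 0-based row-major `(row, col)` grid coordinates to probe
#' identifiers, with optional per-feature channel and intensity-level
#' annotation (used by the image-encoding pipeline). The grid matches the
#' synthesis device: one feature per micromirror for a photolithographic
#' array (1024 x 768 for the XGA device).
#'
#' @slot nRows,nCols grid dimensions.
#' @slot features data.frame with columns `row`, `col`, `probe_id`,
#'   `channel`, `level`.
#' @aliases ArrayLayout-class
#' @exportClass ArrayLayout
setClass("ArrayLayout",
  representation(nRows = "integer", nCols = "integer", features = "data.frame"))

setValidity("ArrayLayout", function(object) {
  ft <- object@features
  need <- c("row", "col", "probe_id")
  if (!all(need %in% names(ft)))
    return("features must have columns row, col, probe_id")
  if (nrow(ft) > 0) {
    if (min(ft$row) < 0 || max(ft$row) >= object@nRows ||
        min(ft$col) < 0 || max(ft$col) >= object@nCols)
      return("feature coordinates outside the grid")
    if (anyDuplicated(ft[c("row", "col")]))
      return("duplicate feature coordinates")
  }
  TRUE
})

#' @param nRows,nCols grid dimensions.
#' @param features data.frame with 0-based `row`, `col` plus `probe_id`
#'   (and optionally `channel`, `level`).
#' @rdname ArrayLayout-class
#' @export
arrayLayout <- function(nRows, nCols, features) {
  features$row <- as.integer(features$row)
  features$col <- as.integer(features$col)
  if (is.null(features$channel)) features$channel <- NA_character_
  if (is.null(features$level)) features$level <- NA_integer_
  rownames(features) <- NULL
  new("ArrayLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      features = features)
}

#' Maskless synthesis plan
#'
#' An ordered phosphoramidite cycle schedule with per-cycle boolean
#' micromirror masks. Photodeprotected cycles use BzNPPOC-dN (3 J/cm2,
#' 15 s coupling) or NPPOC-HEG (6 J/cm2, 300 s); acid-deprotected flood
#' cycles use DMTr-dT (no light, 120 s). `FLOOD` cycles have all-on
#' semantics and carry no mask matrix.
#'
#' @slot cycles data.frame with columns `cycle`, `monomer`, `mask`
#'   (mask name, or `NA` for FLOOD), `dose`, `coupling_time`.
#' @slot masks named list of logical matrices (`nRows` x `nCols`).
#' @slot nRows,nCols grid dimensions.
#' @aliases SynthesisPlan-class
#' @exportClass SynthesisPlan
setClass("SynthesisPlan",
  representation(cycles = "data.frame", masks = "list",
                 nRows = "integer", nCols = "integer"))

setValidity("SynthesisPlan", function(object) {
  cy <- object@cycles
  need <- c("cycle", "monomer", "mask", "dose", "coupling_time")
  if (!all(need %in% names(cy)))
    return("cycles must have columns cycle, monomer, mask, dose, coupling_time")
  masked <- cy$mask[!is.na(cy$mask)]
  if (!all(masked %in% names(object@masks)))
    return("every masked cycle must reference a stored mask")
  for (m in object@masks) {
    if (!is.logical(m) || !identical(dim(m), c(object@nRows, object@nCols)))
      return("all masks must be logical nRows x nCols matrices")
  }
  TRUE
})

#' Per-feature scan intensity table
#'
#' One row per scanned feature per channel: grid position, resolved probe
#' identifier, emission channel (`"532"` Cy3, `"635"` Cy5, `"488"` FAM),
#' foreground and local background intensity.
#'
#' @slot data data.frame with columns `row`, `col`, `probe_id`, `channel`,
#'   `F`, `B`.
#' @slot arm name of the experimental arm the scan belongs to.
#' @aliases ScanTable-class
#' @exportClass ScanTable
setClass("ScanTable",
  representation(data = "data.frame", arm = "character"),
  prototype(arm = "scan"))

setValidity("ScanTable", function(object) {
  d <- object@data
  need <- c("row", "col", "probe_id", "channel", "F", "B")
  if (!all(need %in% names(d)))
    return("data must have columns row, col, probe_id, channel, F, B")
  if (nrow(d) > 0 && (min(d$F) < 0 || min(d$B) < 0))
    return("intensities must be >= 0")
  TRUE
})

#' @param data feature intensity data.frame (see slots).
#' @param arm arm name.
#' @rdname ScanTable-class
#' @export
scanTable <- function(data, arm = "scan") {
  rownames(data) <- NULL
  new("ScanTable", data = data, arm = arm)
}

#' Scan simulation parameters
#'
#' Signal model for synthetic scans. A transcribable feature's expected
#' specific signal is `amplitude * multiplier * s(L)` where
#' `s(L) = L / (halfSat + L)` is a saturating duplex-length response of
#' the probe-overlap length `L`; in Cy3-UTP mode the length response is
#' replaced by the surface-distance decay
#' `d(pos) = max(decay^(pos-1), plateau)` at the feature's annotated rU
#' extension position. Multiplicative lognormal noise with coefficient of
#' variation `cv` (unit mean), additive background around `background`.
#'
#' @slot amplitude full-scale fluorescence amplitude (a.u.).
#' @slot halfSat half-saturation duplex length (nt).
#' @slot decay per-nt distance decay factor.
#' @slot plateau floor of the distance decay (fraction of position 1).
#' @slot efficiency conversion efficiency in `[0, 1]`.
#' @slot background mean background intensity (a.u.).
#' @slot cv lognormal noise coefficient of variation (>= 0).
#' @slot seed RNG seed (mandatory).
#' @aliases SimParams-class
#' @exportClass SimParams
setClass("SimParams",
  representation(amplitude = "numeric", halfSat = "numeric", decay = "numeric",
                 plateau = "numeric", efficiency = "numeric",
                 background = "numeric", cv = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  if (object@efficiency < 0 || object@efficiency > 1)
    return("efficiency must be in [0, 1]")
  if (object@plateau < 0 || object@plateau > 1)
    return("plateau must be in [0, 1]")
  if (object@decay <= 0 || object@decay > 1)
    return("decay must be in (0, 1]")
  if (object@cv < 0) return("cv must be >= 0")
  if (object@amplitude < 0 || object@background < 0)
    return("amplitude and background must be >= 0")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("a seed is mandatory")
  TRUE
})

#' @param amplitude,halfSat,decay,plateau,efficiency,background,cv,seed
#'   see the class slots; defaults model a well-behaved GenePix-class scan
#'   (decay/plateau follow the published positional profile; cv 0.2 is
#'   typical scan-to-scan fluorescence noise).
#' @rdname SimParams-class
#' @export
simParams <- function(amplitude = 10000, halfSat = 8, decay = 0.96,
                      plateau = 0.70, efficiency = 1, background = 100,
                      cv = 0.2, seed) {
  if (missing(seed)) stop("simParams: a seed is mandatory")
  new("SimParams", amplitude = amplitude, halfSat = halfSat, decay = decay,
      plateau = plateau, efficiency = efficiency, background = background,
      cv = cv, seed = as.integer(seed))
}
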