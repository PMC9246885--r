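# Generics and accessors. Slot access from user code goes through these.

#' @rdname oligoSequence
#' @export
setGeneric("oligoSequence", function(x, ...) standardGeneric("oligoSequence"))

#' @rdname oligoSegments
#' @export
setGeneric("oligoSegments", function(x) standardGeneric("oligoSegments"))

#' @rdname oligoLength
#' @export
setGeneric("oligoLength", function(x) standardGeneric("oligoLength"))

#' @rdname templates
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' @rdname templates
#' @export
setGeneric("replicateCount", function(x) standardGeneric("replicateCount"))

#' @rdname templates
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname layoutFeatures
#' @export
setGeneric("layoutFeatures", function(x) standardGeneric("layoutFeatures"))

#' @rdname layoutFeatures
#' @export
setGeneric("layoutDims", function(x) standardGeneric("layoutDims"))

#' @rdname planCycles
#' @export
setGeneric("planCycles", function(x) standardGeneric("planCycles"))

#' @rdname planCycles
#' @export
setGeneric("planMasks", function(x) standardGeneric("planMasks"))

#' @rdname scanData
#' @export
setGeneric("scanData", function(x) standardGeneric("scanData"))

#' Full concatenated sequence of a chimeric oligo
#'
#' @param x a [ChimericOligo-class], [PrimerSpec-class] or
#'   [TemplateSpec-class].
#' @param ... unused.
#' @return A single 5'->3' sequence string (chemistry mix is flattened;
#'   use [oligoSegments()] to retain per-segment chemistry).
#' @name oligoSequence
#' @export
setMethod("oligoSequence", "ChimericOligo", function(x, ...) {
  paste(x@segments$seq, collapse = "")
})

#' @name oligoSequence
#' @export
setMethod("oligoSequence", "PrimerSpec", function(x, ...) {
  oligoSequence(x@oligo)
})

#' @name oligoSequence
#' @export
setMethod("oligoSequence", "TemplateSpec", function(x, ...) x@fullSequence)

#' Segment table of a chimeric oligo
#'
#' @param x a [ChimericOligo-class].
#' @return data.frame with columns `seq`, `chem`.
#' @name oligoSegments
#' @export
setMethod("oligoSegments", "ChimericOligo", function(x) x@segments)

#' Total length of an oligo
#'
#' @param x a [ChimericOligo-class] or [PrimerSpec-class].
#' @return Total length in nt (sum of segment lengths).
#' @name oligoLength
#' @export
setMethod("oligoLength", "ChimericOligo", function(x) {
  sum(nchar(x@segments$seq))
})

#' @name oligoLength
#' @export
setMethod("oligoLength", "PrimerSpec", function(x) oligoLength(x@oligo))

#' DesignTable accessors
#'
#' @param x a [DesignTable-class].
#' @return `templates()` the probe data.frame; `replicateCount()` intended
#'   replicates per probe; `probeIds()` the probe identifiers.
#' @name templates
#' @export
setMethod("templates", "DesignTable", function(x) x@templates)

#' @name templates
#' @export
setMethod("replicateCount", "DesignTable", function(x) x@replicateCount)

#' @name templates
#' @export
setMethod("probeIds", "DesignTable", function(x) x@templates$probe_id)

#' ArrayLayout accessors
#'
#' @param x an [ArrayLayout-class].
#' @return `layoutFeatures()` the feature data.frame (0-based `row`,
#'   `col`); `layoutDims()` `c(nRows, nCols)`.
#' @name layoutFeatures
#' @export
setMethod("layoutFeatures", "ArrayLayout", function(x) x@features)

#' @name layoutFeatures
#' @export
setMethod("layoutDims", "ArrayLayout", function(x) c(x@nRows, x@nCols))

#' SynthesisPlan accessors
#'
#' @param x a [SynthesisPlan-class].
#' @return `planCycles()` the cycle manifest data.frame; `planMasks()` the
#'   named list of logical mask matrices.
#' @name planCycles
#' @export
setMethod("planCycles", "SynthesisPlan", function(x) x@cycles)

#' @name planCycles
#' @export
setMethod("planMasks", "SynthesisPlan", function(x) x@masks)

#' ScanTable accessor
#'
#' @param x a [ScanTable-class].
#' @return The per-feature intensity data.frame.
#' @name scanData
#' @export
setMethod("scanData", "ScanTable", function(x) x@data)

setMethod("show", "ChimericOligo", function(object) {
  seg <- object@segments
  cat(sprintf("ChimericOligo, %d nt in %d segment(s) [5'%s / 3'%s]\n",
              sum(nchar(seg$seq)), nrow(seg), object@label5, object@label3))
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  [%s] %s\n", seg$chem[i], seg$seq[i]))
})

setMethod("show", "PrimerSpec", function(object) {
  cat(sprintf("PrimerSpec '%s': 5'-Ps-%s (2'-OMe, %d nt)\n", object@name,
              oligoSequence(object), oligoLength(object)))
})

setMethod("show", "TemplateSpec", function(object) {
  cat(sprintf("TemplateSpec '%s' (%s), dT%d linker, %d nt\n  5'-%s-3'\n",
              object@probeId, object@role, object@linkerLen,
              nchar(object@fullSequence), object@fullSequence))
  if (!is.na(object@ruPosition))
    cat(sprintf("  rU extension position: %d\n", as.integer(object@ruPosition)))
})

setMethod("show", "DesignTable", function(object) {
  tl <- object@templates
  cat(sprintf("DesignTable: %d probes (%d transcribable, %d control), %d replicate(s) each\n",
              nrow(tl), sum(tl$role == "transcribable"),
              sum(tl$role == "control"), object@replicateCount))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout: %d x %d grid, %d features, %d unique probes\n",
              object@nRows, object@nCols, nrow(object@features),
              length(unique(object@features$probe_id))))
})

setMethod("show", "SynthesisPlan", function(object) {
  cy <- object@cycles
  cat(sprintf("SynthesisPlan: %d cycles (%d masked, %d flood) on %d x %d grid\n",
              nrow(cy), sum(!is.na(cy$mask)), sum(is.na(cy$mask)),
              object@nRows, object@nCols))
})

setMethod("show", "ScanTable", function(object) {
  cat(sprintf("ScanTable '%s': %d feature rows, channel(s) %s\n", object@arm,
              nrow(object@data),
              paste(unique(object@data$channel), collapse = ", ")))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(paste0("SimParams: A=%g, K=%g nt, decay=%g/nt (plateau %g), ",
                     "e=%g, b=%g, CV=%g, seed=%d\n"),
              object@amplitude, object@halfSat, object@decay, object@plateau,
              object@efficiency, object@background, object@cv, object@seed))
})
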