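# Synthetic scan generation with the signal structure the quantification
# pipeline assumes: saturating duplex-length response, surface-distance
# decay for Cy3-UTP incorporation, per-arm class multipliers, lognormal
# multiplicative noise, additive background.

#' Duplex-length intensity response
#'
#' Saturating (Michaelis-type) response `s(L) = L / (K + L)`: intensity
#' grows with probe-overlap length and saturates, as observed for
#' hybridization to truncation series.
#'
#' @param L probe-overlap length(s), nt.
#' @param halfSat half-saturation length K, nt.
#' @return Response fraction(s) in `[0, 1)`.
#' @export
duplexResponse <- function(L, halfSat = 8) L / (halfSat + L)

#' Surface-distance decay of incorporated-label fluorescence
#'
#' `d(pos) = max(decay^(pos - 1), plateau)`: fluorescence of a label
#' incorporated at extension position `pos` (1 = surface-proximal) decays
#' with distance from the surface and levels off at `plateau`.
#'
#' @param pos extension position(s), 1-based.
#' @param decay per-nt decay factor.
#' @param plateau decay floor (fraction of position 1).
#' @return Relative fluorescence in `(0, 1]`.
#' @export
distanceDecay <- function(pos, decay = 0.96, plateau = 0.70) {
  pmax(decay^(pos - 1), plateau)
}

#' Experimental arm descriptors for scan simulation
#'
#' An arm fixes, per probe role, the multiplier applied to the full-scale
#' specific signal, plus the signal mode. Convenience constructors cover
#' the assay designs the quantification pipeline analyses:
#' \describe{
#'   \item{`armConvertedRNA(e)`}{subarray converted to RNA and probed with
#'     the labelled detection oligo: transcribable features carry RNA at
#'     conversion efficiency `e`; DNA controls are DNase-degraded (0).}
#'   \item{`armUntreatedDNA()`}{untreated reference subarray: the ssDNA
#'     controls hybridize the probe at full strength; transcribable
#'     features do not bind it.}
#'   \item{`armDegradation(r, role)`}{DNase (or buffer, `r = 1`) treatment
#'     arm: the targeted probe class retains residual fraction `r`.}
#'   \item{`armCy3Walk()`}{Cy3-UTP incorporation readout of a dA-walk
#'     array: transcribable features fluoresce per their annotated rU
#'     position; controls see background only.}
#' }
#'
#' @param name arm name (becomes the ScanTable arm).
#' @param transcribable,control specific-signal multipliers per role.
#' @param mode `"hybridization"` (duplex-length response) or `"cy3utp"`
#'   (distance-decay response at the annotated rU position).
#' @return list descriptor consumed by [simulateScan()].
#' @export
scanArm <- function(name, transcribable = 1, control = 0,
                    mode = c("hybridization", "cy3utp")) {
  list(name = name, mode = match.arg(mode),
       mult = c(transcribable = transcribable, control = control))
}

#' @param e conversion efficiency in `[0, 1]`.
#' @rdname scanArm
#' @export
armConvertedRNA <- function(name = "converted", e) {
  scanArm(name, transcribable = e, control = 0)
}

#' @rdname scanArm
#' @export
armUntreatedDNA <- function(name = "untreated") {
  scanArm(name, transcribable = 0, control = 1)
}

#' @param r residual signal fraction after treatment.
#' @param role probe class the treatment acts on.
#' @rdname scanArm
#' @export
armDegradation <- function(name, r, role = c("transcribable", "control")) {
  role <- match.arg(role)
  m <- c(transcribable = 1, control = 1)
  m[role] <- r
  scanArm(name, transcribable = m[["transcribable"]],
          control = m[["control"]])
}

#' @rdname scanArm
#' @export
armCy3Walk <- function(name = "cy3walk") {
  scanArm(name, transcribable = 1, control = 0, mode = "cy3utp")
}

#' Simulate scans of a layout under one or more experimental arms
#'
#' Expected foreground of a feature with specific-signal multiplier `m`
#' is `amplitude * m * response + background`, where `response` is the
#' duplex-length response `s(L)` of the probe's variable-region length in
#' hybridization mode, or the distance decay `d(ruPosition)` in Cy3-UTP
#' mode (controls have no incorporated label there and read background
#' only). Multiplicative lognormal noise of unit mean and coefficient of
#' variation `cv` acts on the specific signal; the background draw is
#' normal around `background` (sd `0.1 * background`), floored at 0. With
#' `cv = 0` the scan is exactly noise-free. All randomness derives from
#' `params@seed`, so equal seeds give byte-identical tables.
#'
#' @param layout an [ArrayLayout-class].
#' @param design the companion [DesignTable-class].
#' @param params a [SimParams-class].
#' @param arms list of arm descriptors (see [scanArm()]).
#' @param channel emission channel label for the output rows.
#' @return Named list of [ScanTable-class] objects, one per arm.
#' @export
simulateScan <- function(layout, design, params, arms, channel = "532") {
  stopifnot(is(layout, "ArrayLayout"), is(design, "DesignTable"),
            is(params, "SimParams"))
  if (!is.null(arms$name)) arms <- list(arms)  # single arm passed bare
  feat <- layoutFeatures(layout)
  tl <- templates(design)
  idx <- match(feat$probe_id, tl$probe_id)
  if (anyNA(idx))
    stop(sprintf("simulateScan: unresolved probe_id(s): %s",
                 paste(utils::head(unique(feat$probe_id[is.na(idx)]), 3),
                       collapse = ", ")))
  role <- tl$role[idx]
  if (any(!role %in% ROLES)) stop("simulateScan: unknown probe role")
  vlen <- nchar(tl$variable[idx])
  rupos <- tl$ru_position[idx]
  n <- nrow(feat)
  cv <- params@cv
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(params@seed)
  out <- list()
  for (arm in arms) {
    resp <- if (arm$mode == "hybridization") {
      duplexResponse(vlen, params@halfSat)
    } else {
      r <- ifelse(role == "transcribable" & !is.na(rupos),
                  distanceDecay(rupos, params@decay, params@plateau), 0)
      if (any(role == "transcribable" & is.na(rupos)))
        stop("simulateScan: cy3utp arm needs rU-position annotations on transcribable probes")
      r
    }
    specific <- params@amplitude * unname(arm$mult[role]) * resp
    if (cv > 0) {
      noise <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      bg <- pmax(0, stats::rnorm(n, params@background,
                                 0.1 * params@background))
    } else {
      noise <- rep(1, n)
      bg <- rep(params@background, n)
    }
    d <- data.frame(row = feat$row, col = feat$col,
                    probe_id = feat$probe_id, channel = channel,
                    F = specific * noise + bg, B = bg,
                    stringsAsFactors = FALSE)
    out[[arm$name]] <- scanTable(d, arm = arm$name)
  }
  out
}
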