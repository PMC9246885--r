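# Scan quantification: replicate aggregation, control subtraction,
# max-normalization, ratio estimators with bootstrap CIs, positional
# incorporation profile.

#' Aggregate replicate features per probe
#'
#' Mean and standard deviation of foreground intensity across the
#' replicate features of each probe, per channel. The optional dust rule
#' excludes replicates more than `madLimit` median absolute deviations
#' above the probe median (high outliers only, mirroring dust specks on a
#' scan); exclusions are counted, never silently dropped.
#'
#' @param scan a [ScanTable-class].
#' @param design optional [DesignTable-class]; when supplied, probe ids
#'   are checked against it and probes absent from the scan produce a
#'   missing-probe warning (they are omitted from the result).
#' @param excludeOutliers apply the dust rule (default off).
#' @param madLimit MAD multiplier for the dust rule.
#' @return data.frame with one row per probe per channel: `probe_id`,
#'   `channel`, `n`, `mean`, `sd`, `n_excluded`, and a `values`
#'   list-column holding the retained replicate intensities.
#' @export
aggregateScan <- function(scan, design = NULL, excludeOutliers = FALSE,
                          madLimit = 5) {
  stopifnot(is(scan, "ScanTable"))
  d <- scanData(scan)
  if (!is.null(design)) {
    unknown <- setdiff(d$probe_id, probeIds(design))
    if (length(unknown) > 0)
      stop(sprintf("aggregateScan: scan probe(s) not in the design: %s",
                   paste(utils::head(unknown, 3), collapse = ", ")))
    miss <- setdiff(probeIds(design), d$probe_id)
    if (length(miss) > 0)
      warning(sprintf("aggregateScan: %d probe(s) missing from the scan: %s",
                      length(miss),
                      paste(utils::head(miss, 3), collapse = ", ")))
  }
  key <- interaction(d$probe_id, d$channel, drop = TRUE)
  groups <- split(seq_len(nrow(d)), key)
  rows <- lapply(groups, function(ii) {
    v <- d$F[ii]
    nExcl <- 0L
    if (excludeOutliers && length(v) > 2) {
      md <- stats::median(v)
      mad_ <- stats::mad(v)
      if (mad_ > 0) {
        keep <- v <= md + madLimit * mad_
        nExcl <- sum(!keep)
        v <- v[keep]
      }
    }
    data.frame(probe_id = d$probe_id[ii[1]], channel = d$channel[ii[1]],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_excluded = nExcl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$values <- I(lapply(groups, function(ii) {
    v <- d$F[ii]
    if (excludeOutliers && length(v) > 2) {
      md <- stats::median(v); mad_ <- stats::mad(v)
      if (mad_ > 0) v <- v[v <= md + madLimit * mad_]
    }
    v
  }))
  rownames(out) <- NULL
  out
}

#' Control subtraction and max-normalization
#'
#' Averaged control intensities are subtracted from the matched template
#' intensities (floored at 0 — negative corrected intensities are not
#' physically meaningful) and the corrected values are normalized to the
#' highest corrected signal.
#'
#' @param templateMeans named numeric vector of per-template mean
#'   intensities.
#' @param controlMeans named numeric vector of per-control mean
#'   intensities.
#' @param pairing data.frame with columns `template`, `control` naming
#'   the control of corresponding type for each template; by default
#'   templates are paired positionally.
#' @return data.frame: `template`, `corrected`, `normalized`.
#' @examples
#' backgroundCorrectNormalize(c(a = 100, b = 80), c(ca = 20, cb = 20),
#'                            data.frame(template = c("a", "b"),
#'                                       control = c("ca", "cb")))
#' @export
backgroundCorrectNormalize <- function(templateMeans, controlMeans,
                                       pairing = NULL) {
  if (is.null(pairing)) {
    if (length(controlMeans) == 1)
      controlMeans <- rep(controlMeans, length(templateMeans))
    if (length(templateMeans) != length(controlMeans))
      stop("backgroundCorrectNormalize: unpaired template/control vectors")
    corrected <- pmax(templateMeans - controlMeans, 0)
    tnames <- names(templateMeans)
    if (is.null(tnames)) tnames <- as.character(seq_along(templateMeans))
  } else {
    ti <- match(pairing$template, names(templateMeans))
    ci <- match(pairing$control, names(controlMeans))
    if (anyNA(ti) || anyNA(ci))
      stop("backgroundCorrectNormalize: pairing references unknown probes")
    corrected <- pmax(templateMeans[ti] - controlMeans[ci], 0)
    tnames <- pairing$template
  }
  mx <- max(corrected)
  if (mx <= 0)
    stop("backgroundCorrectNormalize: all corrected intensities <= 0; normalization is degenerate")
  data.frame(template = tnames, corrected = unname(corrected),
             normalized = unname(corrected) / mx, stringsAsFactors = FALSE)
}

.bootRatio <- function(num, den, numBg = 0, denBg = 0, nBoot = 1000,
                       seed = 1, conf = 0.95, scale = 1) {
  denMean <- mean(den) - denBg
  if (denMean <= 0)
    stop("ratio undefined: denominator mean <= 0 after background subtraction")
  est <- (mean(num) - numBg) / denMean * scale
  set.seed(seed)
  boots <- vapply(seq_len(nBoot), function(b) {
    nm <- mean(sample(num, replace = TRUE)) - numBg
    dm <- mean(sample(den, replace = TRUE)) - denBg
    if (dm <= 0) NA_real_ else nm / dm * scale
  }, numeric(1))
  ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, lo = ci[1], hi = ci[2], boots = boots)
}

.ratioEstimator <- function(numStats, denStats, pairing, numBackground,
                            denBackground, nBoot, seed, conf, scale,
                            estimateName) {
  ni <- match(pairing[[1]], numStats$probe_id)
  di <- match(pairing[[2]], denStats$probe_id)
  if (anyNA(ni) || anyNA(di))
    stop("pairing references probes absent from the aggregated statistics")
  perPair <- vector("list", nrow(pairing))
  bootMat <- matrix(NA_real_, nBoot, nrow(pairing))
  for (p in seq_len(nrow(pairing))) {
    r <- .bootRatio(numStats$values[[ni[p]]], denStats$values[[di[p]]],
                    numBackground, denBackground, nBoot = nBoot,
                    seed = seed + p, conf = conf, scale = scale)
    perPair[[p]] <- data.frame(pairing[p, , drop = FALSE],
                               estimate = r$estimate, lo = r$lo, hi = r$hi,
                               stringsAsFactors = FALSE)
    bootMat[, p] <- r$boots
  }
  pairs <- do.call(rbind, perPair)
  rownames(pairs) <- NULL
  summaryBoots <- rowMeans(bootMat, na.rm = TRUE)
  ci <- stats::quantile(summaryBoots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  summary <- list(mean(pairs$estimate), lo = ci[1], hi = ci[2])
  names(summary)[1] <- estimateName
  list(pairs = pairs, summary = summary)
}

#' Conversion efficiency from matched RNA / DNA-reference scans
#'
#' Efficiency of the DNA-to-RNA conversion, per matched probe pair, as
#' the ratio of mean hybridization signal on converted RNA features to
#' mean signal on the ssDNA reference features of the same sequence on an
#' untreated subarray, expressed in percent. Uncertainty comes from a
#' seeded bootstrap over replicates (the published workflow reports no
#' error model for its ratios).
#'
#' @param rnaStats [aggregateScan()] output for the converted subarray.
#' @param dnaStats [aggregateScan()] output for the untreated reference
#'   subarray.
#' @param pairing data.frame with columns `rna`, `dna` (probe ids).
#' @param rnaBackground,dnaBackground scalar background estimates
#'   subtracted from the respective means before the ratio (e.g. the mean
#'   of the degraded controls on the converted arm and of the
#'   non-hybridizing templates on the untreated arm).
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param conf CI level.
#' @return list: `pairs` (per-pair estimate with CI, in %), `summary`
#'   (`efficiency` = mean over pairs, with bootstrap CI).
#' @export
conversionEfficiency <- function(rnaStats, dnaStats, pairing,
                                 rnaBackground = 0, dnaBackground = 0,
                                 nBoot = 1000, seed = 1, conf = 0.95) {
  .ratioEstimator(rnaStats, dnaStats, pairing[, c("rna", "dna")],
                  rnaBackground, dnaBackground, nBoot, seed, conf,
                  scale = 100, estimateName = "efficiency")
}

#' Degradation residual from treated / buffer scans
#'
#' Residual signal fraction after enzymatic treatment: mean(treated) /
#' mean(buffer) per matched probe, with seeded bootstrap CI. A residual
#' of 0.25 means 25% of the buffer-control signal survives.
#'
#' @param treatedStats,bufferStats [aggregateScan()] outputs for the
#'   treated and buffer-control arms.
#' @param pairing data.frame with columns `treated`, `buffer` (probe
#'   ids; usually identical).
#' @param treatedBackground,bufferBackground scalar background estimates.
#' @inheritParams conversionEfficiency
#' @return list: `pairs`, `summary` (`residual` = mean over pairs).
#' @export
degradationResidual <- function(treatedStats, bufferStats, pairing,
                                treatedBackground = 0, bufferBackground = 0,
                                nBoot = 1000, seed = 1, conf = 0.95) {
  .ratioEstimator(treatedStats, bufferStats,
                  pairing[, c("treated", "buffer")],
                  treatedBackground, bufferBackground, nBoot, seed, conf,
                  scale = 1, estimateName = "residual")
}

#' Positional incorporation profile of a dA-walk scan
#'
#' Full published recipe for the Cy3-UTP readout: replicate averaging,
#' subtraction of the matched no-primer-complement control of each
#' variant, normalization to the highest corrected signal, then
#' re-expression relative to the surface-proximal (position 1) variant.
#' Also reports the mean relative intensity over the final 20 extension
#' positions, the plateau diagnostic of full-length synthesis.
#'
#' @param scan a Cy3-UTP [ScanTable-class] of a dA-walk array.
#' @param design the dA-walk [DesignTable-class] (rU-position annotated,
#'   with matched `walkctrl_*` controls).
#' @param excludeOutliers,madLimit passed to [aggregateScan()].
#' @return list: `profile` (data.frame `position`, `corrected`,
#'   `normalized`, `relative`), `final20Mean` (mean `relative` over
#'   positions within 20 nt of the distal end).
#' @export
positionalProfile <- function(scan, design, excludeOutliers = FALSE,
                              madLimit = 5) {
  stopifnot(is(design, "DesignTable"))
  tl <- templates(design)
  tpl <- tl[tl$role == "transcribable" & !is.na(tl$ru_position), ,
            drop = FALSE]
  ctl <- tl[tl$role == "control" & !is.na(tl$ru_position), , drop = FALSE]
  if (nrow(tpl) == 0)
    stop("positionalProfile: design carries no rU-position annotations")
  stats_ <- aggregateScan(scan, excludeOutliers = excludeOutliers,
                          madLimit = madLimit)
  tmeans <- stats::setNames(
    stats_$mean[match(tpl$probe_id, stats_$probe_id)], tpl$probe_id)
  cmatch <- ctl$probe_id[match(tpl$ru_position, ctl$ru_position)]
  cmeans <- stats::setNames(
    stats_$mean[match(cmatch, stats_$probe_id)], cmatch)
  if (anyNA(tmeans) || anyNA(cmeans))
    stop("positionalProfile: scan is missing dA-walk probes")
  bc <- backgroundCorrectNormalize(tmeans, cmeans)
  prof <- data.frame(position = tpl$ru_position, corrected = bc$corrected,
                     normalized = bc$normalized)
  prof <- prof[order(prof$position), , drop = FALSE]
  ref <- prof$normalized[prof$position == 1]
  if (length(ref) != 1 || ref <= 0)
    stop("positionalProfile: position-1 reference variant missing or zero")
  prof$relative <- prof$normalized / ref
  rownames(prof) <- NULL
  finalWin <- prof$position > max(prof$position) - 20
  list(profile = prof, final20Mean = mean(prof$relative[finalWin]))
}
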