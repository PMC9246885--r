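# RGB bitmap -> per-channel truncation-level array layout.

#' Channel template sequences
#'
#' The three variable regions representing the red (Cy5), green (Cy3) and
#' blue (FAM) channels of the RGB encoding. All share the common
#' primer-complement + dT5 block at the 3' end once built into templates.
#'
#' @return Named character vector (`red`, `green`, `blue`).
#' @examples
#' nchar(channelTemplates())  # 25, 20, 24
#' @export
channelTemplates <- function() {
  c(red   = "TCACCGAATCGATTCCATCTGCTTC",
    green = "TCAACCCAGGTCCAATTTCC",
    blue  = "ACAGTGGATCGTACTCAGGTCTCA")
}

#' Quantize an 8-bit RGB raster to k brightness levels
#'
#' Floor binning: `level = floor(value * k / 256)`, mapping 0..255 onto
#' 0..k-1. Floor (not rounding) is used so encoded layouts are exactly
#' reproducible from the integer pixel values.
#'
#' @param image numeric array `h x w x 3` of 8-bit values (0..255).
#' @param k number of levels per channel, in `[2, 256]`.
#' @return list of integer level matrices `red`, `green`, `blue`.
#' @examples
#' img <- array(c(0, 128, 255), c(1, 1, 3))
#' quantizeRGB(img)  # levels 0, 4, 7
#' @export
quantizeRGB <- function(image, k = 8L) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("quantizeRGB: input must be an h x w x 3 RGB array")
  if (k < 2 || k > 256) stop("quantizeRGB: k must be in [2, 256]")
  if (min(image) < 0 || max(image) > 255)
    stop("quantizeRGB: 8-bit channel values (0..255) required")
  lev <- function(m) matrix(as.integer(floor(m * k / 256)),
                            nrow = dim(image)[1])
  list(red = lev(image[, , 1]), green = lev(image[, , 2]),
       blue = lev(image[, , 3]))
}

#' Select k truncation lengths spanning the intensity range uniformly
#'
#' Given a calibration curve of truncation length -> mean hybridization
#' intensity, picks the k lengths whose intensities best match k targets
#' evenly spaced from the minimum to the maximum observed intensity
#' (both extremes included), minimizing the sum of squared deviations
#' with the selected lengths sorted ascending and assigned to levels
#' 0 (dimmest) .. k-1 (brightest). The optimum is global over all size-k
#' subsets; ties break to the lexicographically smallest length tuple.
#'
#' @param curve data.frame with columns `length` (nt, strictly positive)
#'   and `intensity` (>= 0).
#' @param k number of levels (default 8).
#' @return Integer vector of k truncation lengths, level 0 first.
#' @examples
#' curve <- data.frame(length = 1:20, intensity = 1:20)
#' selectLevels(curve, 8)  # 1 4 6 9 12 15 17 20
#' @export
selectLevels <- function(curve, k = 8L) {
  if (!all(c("length", "intensity") %in% names(curve)))
    stop("selectLevels: curve needs columns 'length' and 'intensity'")
  if (any(curve$length <= 0)) stop("selectLevels: lengths must be positive")
  if (any(curve$intensity < 0)) stop("selectLevels: intensities must be >= 0")
  n <- nrow(curve)
  if (n < k)
    stop(sprintf("selectLevels: insufficient calibration: %d point(s) for k = %d",
                 n, k))
  ord <- order(curve$length)
  len <- curve$length[ord]
  if (anyDuplicated(len)) stop("selectLevels: duplicate calibration lengths")
  intens <- curve$intensity[ord]
  targets <- seq(min(intens), max(intens), length.out = k)
  if (n == k) return(as.integer(len))
  # Exact DP: candidates in ascending length order; the j-th selected
  # length is scored against target j, which is precisely the subset
  # objective. B[i, j] = best cost of covering targets j..k using
  # candidates i..n with candidate i taken as level j-1.
  cost <- outer(intens, targets, function(x, t) (x - t)^2)
  B <- matrix(Inf, n, k)
  B[, k] <- cost[, k]
  for (j in (k - 1):1) {
    # suffix minima of B[, j + 1]
    suf <- rev(cummin(rev(B[, j + 1])))
    for (i in 1:(n - (k - j))) B[i, j] <- cost[i, j] + suf[i + 1]
  }
  tol <- 1e-9
  pick <- integer(k)
  best <- min(B[, 1])
  lo <- 1L
  target <- best
  for (j in 1:k) {
    cand <- which(B[, j] <= target + tol)
    cand <- cand[cand >= lo & cand <= n - (k - j)]
    pick[j] <- cand[1]
    if (j < k) {
      target <- target - cost[pick[j], j]
      lo <- pick[j] + 1L
    }
  }
  as.integer(len[pick])
}

#' Encode quantized level rasters as an array layout
#'
#' Expands every image pixel into a block of features (default 2 x 2:
#' red, green, blue, plus a duplicate of the pixel's brightest channel in
#' the fourth position) and tiles the expanded image across the synthesis
#' grid (default 2 x 2 tiling, so a 192 x 256 pixel source exactly fills
#' the 768 x 1024 photolithography grid). Each feature receives the
#' template for its channel truncated to the pixel's level; level-0
#' (black) pixels receive the shared untranscribable dark control, which
#' guarantees zero specific signal. Truncations preserve the 3' (primer-
#' adjacent) end: the level-L variable region is the 3'-most `lengths[L+1]`
#' characters of the channel sequence.
#'
#' @param levels list of integer level matrices (`red`, `green`, `blue`),
#'   as from [quantizeRGB()].
#' @param levelMaps named list of increasing truncation-length vectors per
#'   channel (one per level), as from [selectLevels()].
#' @param primer a [PrimerSpec-class].
#' @param linkerLen dT linker length for the emitted templates.
#' @param blockDim pixel expansion factors `c(rows, cols)`.
#' @param tileDim image tiling factors `c(rows, cols)`.
#' @param grid optional expected grid size `c(nRows, nCols)`; an error
#'   naming both shapes is raised when the expanded/tiled raster differs.
#' @return list with `layout` (an [ArrayLayout-class]) and `design` (a
#'   [DesignTable-class] of the emitted channel truncation templates plus
#'   the dark control).
#' @export
encodeImage <- function(levels, levelMaps, primer = defaultPrimer(),
                        linkerLen = 5L, blockDim = c(2L, 2L),
                        tileDim = c(2L, 2L), grid = NULL) {
  chans <- c("red", "green", "blue")
  if (!all(chans %in% names(levels)))
    stop("encodeImage: levels must contain red, green and blue matrices")
  if (!all(chans %in% names(levelMaps)))
    stop("encodeImage: levelMaps must contain red, green and blue maps")
  h <- nrow(levels$red); w <- ncol(levels$red)
  for (ch in chans)
    if (!identical(dim(levels[[ch]]), c(h, w)))
      stop("encodeImage: channel rasters differ in shape")
  k <- length(levelMaps$red)
  for (ch in chans) {
    lm <- levelMaps[[ch]]
    if (is.unsorted(lm, strictly = TRUE))
      stop("encodeImage: level maps must be strictly increasing")
    if (max(levels[[ch]]) >= length(lm))
      stop("encodeImage: raster level exceeds the level map")
  }
  nR <- h * blockDim[1] * tileDim[1]
  nC <- w * blockDim[2] * tileDim[2]
  if (!is.null(grid) && !identical(as.integer(grid), as.integer(c(nR, nC))))
    stop(sprintf("encodeImage: raster %d x %d with block %dx%d and tiling %dx%d gives a %d x %d grid, not %d x %d",
                 h, w, blockDim[1], blockDim[2], tileDim[1], tileDim[2],
                 nR, nC, grid[1], grid[2]))
  if (prod(blockDim) < 3)
    stop("encodeImage: the pixel block must hold at least the three channels")

  # emitted templates: 3 channels x k levels, plus the dark control
  seqs <- channelTemplates()
  specs <- list()
  for (ch in chans) {
    full <- seqs[[ch]]
    for (lv in 0:(k - 1)) {
      L <- levelMaps[[ch]][lv + 1]
      if (L > nchar(full))
        stop(sprintf("encodeImage: %s truncation %d nt exceeds the %d nt channel template",
                     ch, L, nchar(full)))
      v <- substr(full, nchar(full) - L + 1, nchar(full))
      specs[[length(specs) + 1]] <-
        makeTemplate(v, linkerLen, primer, sprintf("%s_L%d", ch, lv),
                     "photolithography")
    }
  }
  specs[[length(specs) + 1]] <-
    makeControl("AGCTTAGCTAGTTACGATCC", linkerLen, primer, "dark",
                "photolithography")
  design <- designTable(specs, replicateCount = 1L,
                        metadata = list(platform = "photolithography",
                                        primer = primer@name,
                                        k = k, blockDim = blockDim,
                                        tileDim = tileDim))

  # per-pixel slot assignment (vectorized over the h*w raster)
  lvR <- as.vector(levels$red); lvG <- as.vector(levels$green)
  lvB <- as.vector(levels$blue)
  lvAll <- cbind(red = lvR, green = lvG, blue = lvB)
  brightIdx <- max.col(lvAll, ties.method = "first")
  slots <- list(list(ch = rep("red", h * w), lv = lvR),
                list(ch = rep("green", h * w), lv = lvG),
                list(ch = rep("blue", h * w), lv = lvB))
  nSlots <- prod(blockDim)
  if (nSlots >= 4) {
    dupLv <- lvAll[cbind(seq_len(h * w), brightIdx)]
    slots[[4]] <- list(ch = chans[brightIdx], lv = dupLv)
    if (nSlots > 4)
      for (s in 5:nSlots) slots[[s]] <- slots[[4]]
  }
  pixRow <- as.vector(row(levels$red)) - 1L
  pixCol <- as.vector(col(levels$red)) - 1L
  slotDr <- (seq_len(nSlots) - 1L) %/% blockDim[2]
  slotDc <- (seq_len(nSlots) - 1L) %% blockDim[2]
  base <- do.call(rbind, lapply(seq_len(nSlots), function(s) {
    ids <- ifelse(slots[[s]]$lv == 0L, "dark",
                  sprintf("%s_L%d", slots[[s]]$ch, slots[[s]]$lv))
    data.frame(row = pixRow * blockDim[1] + slotDr[s],
               col = pixCol * blockDim[2] + slotDc[s],
               probe_id = ids,
               channel = ifelse(slots[[s]]$lv == 0L, NA_character_,
                                slots[[s]]$ch),
               level = slots[[s]]$lv, stringsAsFactors = FALSE)
  }))
  nTiles <- tileDim[1] * tileDim[2]
  tileR <- rep((seq_len(nTiles) - 1L) %/% tileDim[2], each = nrow(base))
  tileC <- rep((seq_len(nTiles) - 1L) %% tileDim[2], each = nrow(base))
  feat <- data.frame(row = rep(base$row, nTiles) + tileR * h * blockDim[1],
                     col = rep(base$col, nTiles) + tileC * w * blockDim[2],
                     probe_id = rep(base$probe_id, nTiles),
                     channel = rep(base$channel, nTiles),
                     level = rep(base$level, nTiles),
                     stringsAsFactors = FALSE)
  list(layout = arrayLayout(nR, nC, feat), design = design)
}

#' Synthetic truncation-length calibration curve
#'
#' Stand-in for the hybridization calibration of all possible 5'
#' truncations of a channel template (the measured curves live outside
#' this package): intensity follows the same saturating duplex-length
#' response the scan simulator uses, `A * L / (K + L)`. Truncations
#' shorter than `minLength` do not form stable duplexes under microarray
#' hybridization conditions and are excluded from the candidate set.
#'
#' @param fullLength full channel template length (nt).
#' @param amplitude saturation intensity (a.u.).
#' @param halfSat half-saturation length (nt).
#' @param minLength shortest usable truncation (nt).
#' @return data.frame with columns `length`, `intensity` for
#'   L = minLength..fullLength.
#' @examples
#' syntheticCalibration(20)
#' @export
syntheticCalibration <- function(fullLength, amplitude = 10000, halfSat = 8,
                                 minLength = 6) {
  L <- seq(minLength, fullLength)
  data.frame(length = L, intensity = amplitude * L / (halfSat + L))
}
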