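# Readers/writers for the external formats the toolkit touches.
# All text formats: tab separators, "\n" endings, UTF-8; numeric output
# at 6 significant digits; writers are deterministic.

.fmtNum <- function(x) formatC(x, digits = 6, format = "g")

.writeLines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Design table TSV and FASTA output
#'
#' The design-TSV dialect has one row per probe with columns `probe_id`,
#' `role`, `linker_len`, `variable`, `full_sequence`, `primer_name`,
#' `ru_position`; `readDesignTSV()` restores a [DesignTable-class]
#' (replicate count and metadata travel in `# key: value` header
#' comments). `writeDesignFASTA()` emits the full probe sequences.
#'
#' @param design a [DesignTable-class].
#' @param path output file.
#' @return `readDesignTSV()` a [DesignTable-class]; writers return the
#'   path invisibly.
#' @export
writeDesignTSV <- function(design, path) {
  stopifnot(is(design, "DesignTable"))
  tl <- templates(design)
  hdr <- sprintf("# replicate_count: %d", replicateCount(design))
  md <- design@metadata
  scalars <- md[vapply(md, function(x) is.atomic(x) && length(x) == 1,
                       logical(1))]
  hdr <- c(hdr, vapply(names(scalars), function(k)
    sprintf("# %s: %s", k, as.character(scalars[[k]])), character(1)))
  body <- c(paste(.DESIGN_COLS, collapse = "\t"),
            vapply(seq_len(nrow(tl)), function(i)
              paste(c(tl$probe_id[i], tl$role[i], tl$linker_len[i],
                      tl$variable[i], tl$full_sequence[i],
                      ifelse(is.na(tl$primer_name[i]), "NA", tl$primer_name[i]),
                      ifelse(is.na(tl$ru_position[i]), "NA",
                             as.character(tl$ru_position[i]))),
                    collapse = "\t"), character(1)))
  .writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeDesignTSV
#' @export
readDesignTSV <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- val
  }
  repc <- if (!is.null(meta$replicate_count)) as.integer(meta$replicate_count)
          else 1L
  meta$replicate_count <- NULL
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1 || !identical(strsplit(body[1], "\t")[[1]], .DESIGN_COLS))
    stop(sprintf("readDesignTSV: malformed header at line %d: expected columns %s",
                 length(hdr) + 1, paste(.DESIGN_COLS, collapse = ", ")))
  tl <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "character", "character",
                                         "character", "numeric"))
  designTable(tl, replicateCount = repc, metadata = meta)
}

#' @rdname writeDesignTSV
#' @export
writeDesignFASTA <- function(design, path) {
  stopifnot(is(design, "DesignTable"))
  tl <- templates(design)
  set <- Biostrings::DNAStringSet(stats::setNames(tl$full_sequence,
                                                  tl$probe_id))
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Read plain sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
readFASTA <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Chimeric oligo tab-delimited serialization
#'
#' One line per oligo: `name`, `label5`, `label3`, then the segment list
#' as `chem:seq` pairs joined by `|`.
#'
#' @param oligos named list of [ChimericOligo-class] objects.
#' @param path file path.
#' @return `readChimeraTSV()` a named list of oligos; the writer returns
#'   the path invisibly.
#' @export
writeChimeraTSV <- function(oligos, path) {
  lines <- c("name\tlabel5\tlabel3\tsegments",
             vapply(names(oligos), function(nm) {
               o <- oligos[[nm]]
               seg <- oligoSegments(o)
               paste(nm, o@label5, o@label3,
                     paste(paste0(seg$chem, ":", seg$seq), collapse = "|"),
                     sep = "\t")
             }, character(1)))
  .writeLines(lines, path)
  invisible(path)
}

#' @rdname writeChimeraTSV
#' @export
readChimeraTSV <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "name\tlabel5\tlabel3\tsegments"))
    stop("readChimeraTSV: malformed header at line 1")
  out <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop(sprintf("readChimeraTSV: expected 4 columns at line %d", i))
    parts <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    chem <- sub(":.*$", "", parts)
    seqs <- sub("^[^:]*:", "", parts)
    out[[f[1]]] <- chimericOligo(seqs, chem, label5 = f[2], label3 = f[3])
  }
  out
}

.atfHeader <- function(type, extraRecords = character(0), nDataCols) {
  records <- c(sprintf("\"Type=%s\"", type), extraRecords)
  c("ATF\t1.0",
    sprintf("%d\t%d", length(records), nDataCols),
    records)
}

#' GenePix Array List (GAL) output and input
#'
#' ATF 1.0 header, then Block / Column / Row / Name / ID columns.
#' GenePix coordinates are 1-based: `Block = 1`, `Column = col + 1`,
#' `Row = row + 1` relative to the 0-based layout grid.
#'
#' @param layout an [ArrayLayout-class].
#' @param design optional [DesignTable-class]; when given, Name carries
#'   the probe role.
#' @param path file path.
#' @return `readGAL()` an [ArrayLayout-class] (grid size inferred from
#'   the maximum coordinates unless `nRows`/`nCols` are given); writers
#'   return the path invisibly.
#' @export
writeGAL <- function(layout, design = NULL, path) {
  stopifnot(is(layout, "ArrayLayout"))
  ft <- layoutFeatures(layout)
  name <- rep("", nrow(ft))
  if (!is.null(design)) {
    tl <- templates(design)
    name <- tl$role[match(ft$probe_id, tl$probe_id)]
    name[is.na(name)] <- ""
  }
  lines <- c(.atfHeader("GenePix ArrayList V1.0", nDataCols = 5),
             "Block\tColumn\tRow\tName\tID",
             sprintf("1\t%d\t%d\t%s\t%s", ft$col + 1L, ft$row + 1L,
                     name, ft$probe_id))
  .writeLines(lines, path)
  invisible(path)
}

.readATF <- function(path, expectType) {
  lines <- readLines(path)
  if (length(lines) < 3 || !grepl("^ATF\t", lines[1]))
    stop(sprintf("%s: not an ATF file (line 1)", basename(path)))
  ver <- strsplit(lines[1], "\t")[[1]][2]
  if (ver != "1.0")
    stop(sprintf("%s: unsupported ATF version '%s'", basename(path), ver))
  counts <- as.integer(strsplit(lines[2], "\t")[[1]])
  nRec <- counts[1]
  records <- lines[2 + seq_len(nRec)]
  if (!any(grepl(expectType, records, fixed = TRUE)))
    stop(sprintf("%s: expected a '%s' record in the ATF header",
                 basename(path), expectType))
  body <- lines[-(seq_len(2 + nRec))]
  utils::read.delim(text = paste(body, collapse = "\n"), check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @param path GAL file.
#' @param nRows,nCols optional grid dimensions.
#' @rdname writeGAL
#' @export
readGAL <- function(path, nRows = NULL, nCols = NULL) {
  d <- .readATF(path, "GenePix ArrayList")
  need <- c("Block", "Column", "Row", "ID")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("readGAL: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  ft <- data.frame(row = d$Row - 1L, col = d$Column - 1L,
                   probe_id = as.character(d$ID), stringsAsFactors = FALSE)
  arrayLayout(if (is.null(nRows)) max(ft$row) + 1L else nRows,
              if (is.null(nCols)) max(ft$col) + 1L else nCols, ft)
}

#' GenePix Results (GPR subset) input and output
#'
#' The dialect covers the columns the quantification pipeline needs:
#' Block, Column, Row, Name, ID, and `F<wavelength> Median` /
#' `B<wavelength> Median` per scanned channel; extra columns pass
#' through `readGPR()` untouched (scanner configurations vary).
#'
#' @param scan a [ScanTable-class] (possibly several channels).
#' @param path file path.
#' @return `readGPR()` a [ScanTable-class]; the writer returns the path
#'   invisibly.
#' @export
writeGPR <- function(scan, path) {
  stopifnot(is(scan, "ScanTable"))
  d <- scanData(scan)
  chans <- sort(unique(d$channel))
  key <- paste(d$row, d$col, sep = "_")
  base <- d[!duplicated(key), c("row", "col", "probe_id")]
  baseKey <- paste(base$row, base$col, sep = "_")
  cols <- c("Block", "Column", "Row", "Name", "ID",
            as.vector(rbind(sprintf("F%s Median", chans),
                            sprintf("B%s Median", chans))))
  mat <- matrix("", nrow(base), 2 * length(chans))
  for (ci in seq_along(chans)) {
    sub <- d[d$channel == chans[ci], ]
    i <- match(paste(sub$row, sub$col, sep = "_"), baseKey)
    mat[i, 2 * ci - 1] <- .fmtNum(sub$F)
    mat[i, 2 * ci] <- .fmtNum(sub$B)
  }
  body <- vapply(seq_len(nrow(base)), function(i)
    paste(c("1", base$col[i] + 1L, base$row[i] + 1L, "", base$probe_id[i],
            mat[i, ]), collapse = "\t"), character(1))
  lines <- c(.atfHeader("GenePix Results 3",
                        sprintf("\"Wavelengths=%s\"",
                                paste(chans, collapse = "\t")),
                        nDataCols = length(cols)),
             paste(cols, collapse = "\t"), body)
  .writeLines(lines, path)
  invisible(path)
}

#' @param path GPR file.
#' @param arm arm label for the resulting [ScanTable-class].
#' @rdname writeGPR
#' @export
readGPR <- function(path, arm = NULL) {
  d <- .readATF(path, "GenePix Results")
  need <- c("Block", "Column", "Row", "ID")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("readGPR: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  fcols <- grep("^F[0-9]+ Median$", names(d), value = TRUE)
  if (length(fcols) == 0)
    stop("readGPR: no 'F<wavelength> Median' foreground column found")
  rows <- list()
  for (fc in fcols) {
    chan <- sub("^F([0-9]+) Median$", "\\1", fc)
    bc <- sprintf("B%s Median", chan)
    rows[[chan]] <- data.frame(row = d$Row - 1L, col = d$Column - 1L,
                               probe_id = as.character(d$ID), channel = chan,
                               F = as.numeric(d[[fc]]),
                               B = if (bc %in% names(d)) as.numeric(d[[bc]])
                                   else 0,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  scanTable(out, arm = if (is.null(arm)) basename(path) else arm)
}

#' Plain tab-delimited scan table
#'
#' Columns `row`, `col`, `probe_id`, `channel`, `F`, `B`; the simple
#' equivalent of the GPR subset.
#'
#' @param scan a [ScanTable-class].
#' @param path file path.
#' @param arm arm label on read.
#' @return `readScanTSV()` a [ScanTable-class].
#' @export
writeScanTSV <- function(scan, path) {
  d <- scanData(scan)
  lines <- c("row\tcol\tprobe_id\tchannel\tF\tB",
             sprintf("%d\t%d\t%s\t%s\t%s\t%s", d$row, d$col, d$probe_id,
                     d$channel, .fmtNum(d$F), .fmtNum(d$B)))
  .writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScanTSV
#' @export
readScanTSV <- function(path, arm = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("integer", "integer", "character",
                                        "character", "numeric", "numeric"))
  if (!identical(names(d), c("row", "col", "probe_id", "channel", "F", "B")))
    stop("readScanTSV: malformed header at line 1")
  scanTable(d, arm = if (is.null(arm)) basename(path) else arm)
}

#' Portable pixmap (PPM) and bitmap (PBM) images
#'
#' `readPPM()` reads binary (P6) and ASCII (P3) 8-bit portable pixmaps
#' into an `h x w x 3` integer array; `writePPM()` writes P6.
#' `writePBM()` / `readPBM()` handle the boolean synthesis masks as P4
#' (binary, default) or P1 (ASCII) portable bitmaps.
#'
#' @param path file path.
#' @return `readPPM()` an integer array `h x w x 3` (0..255); `readPBM()`
#'   a logical matrix.
#' @export
readPPM <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  if (!magic %in% c("P3", "P6"))
    stop(sprintf("readPPM: '%s' is not a P3/P6 portable pixmap", basename(path)))
  tok <- .pnmTokens(con, 3)
  w <- tok[1]; h <- tok[2]; maxv <- tok[3]
  if (maxv > 255) stop("readPPM: only 8-bit pixmaps supported")
  n <- w * h * 3
  vals <- if (magic == "P6") as.integer(readBin(con, "raw", n))
          else .pnmTokens(con, n)
  arr <- array(0L, c(h, w, 3))
  vals <- matrix(vals, nrow = 3)  # interleaved RGB, row-major pixels
  for (ch in 1:3)
    arr[, , ch] <- matrix(vals[ch, ], nrow = h, byrow = TRUE)
  arr
}

.pnmTokens <- function(con, n) {
  out <- integer(0)
  buf <- character(0)
  while (length(out) < n) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || ch == "") stop("unexpected end of PNM header/data")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0) {
      out <- c(out, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  out
}

#' @param image integer array `h x w x 3` (0..255).
#' @rdname readPPM
#' @export
writePPM <- function(image, path) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  inter <- rbind(as.vector(t(image[, , 1])), as.vector(t(image[, , 2])),
                 as.vector(t(image[, , 3])))
  writeBin(as.raw(as.vector(inter)), con)
  invisible(path)
}

#' @param mask logical matrix.
#' @param ascii write P1 (ASCII) instead of P4 (binary).
#' @rdname readPPM
#' @export
writePBM <- function(mask, path, ascii = FALSE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  if (ascii) {
    rows <- apply(mask, 1, function(r) paste(as.integer(r), collapse = " "))
    .writeLines(c("P1", sprintf("%d %d", w, h), rows), path)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(sprintf("P4\n%d %d\n", w, h), con, eos = NULL)
    wBytes <- ceiling(w / 8)
    bits <- matrix(FALSE, h, wBytes * 8)
    bits[, seq_len(w)] <- mask
    bytes <- vapply(seq_len(h), function(i) {
      b <- bits[i, ]
      packed <- vapply(seq_len(wBytes), function(k) {
        sum(b[(k - 1) * 8 + 1:8] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
      }, numeric(1))
      as.raw(packed)
    }, raw(wBytes))
    writeBin(as.vector(bytes), con)
  }
  invisible(path)
}

#' @rdname readPPM
#' @export
readPBM <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  if (!magic %in% c("P1", "P4"))
    stop(sprintf("readPBM: '%s' is not a P1/P4 portable bitmap", basename(path)))
  tok <- .pnmTokens(con, 2)
  w <- tok[1]; h <- tok[2]
  if (magic == "P1") {
    vals <- .pnmTokens(con, w * h)
    return(matrix(as.logical(vals), h, w, byrow = TRUE))
  }
  wBytes <- ceiling(w / 8)
  bytes <- as.integer(readBin(con, "raw", h * wBytes))
  bits <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    rowBytes <- bytes[(i - 1) * wBytes + seq_len(wBytes)]
    rowBits <- as.logical(bitwAnd(rep(rowBytes, each = 8),
                                  rep(c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L),
                                      wBytes)))
    bits[i, ] <- rowBits[seq_len(w)]
  }
  bits
}

#' Read an RGB image (PPM or PNG)
#'
#' @param path image file (`.ppm` P3/P6, or `.png` when the `png`
#'   package is available).
#' @return integer array `h x w x 3` (0..255).
#' @export
readRGBImage <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("readRGBImage: reading PNG needs the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) != 3 || dim(a)[3] < 3)
      stop("readRGBImage: PNG is not an RGB image")
    return(array(as.integer(round(a[, , 1:3] * 255)), dim = c(dim(a)[1:2], 3)))
  }
  readPPM(path)
}

#' Synthesis plan export: mask files plus a cycle manifest
#'
#' Writes one portable bitmap per masked cycle and a tab-delimited
#' manifest (`cycle`, `monomer`, `mask_file` or `FLOOD`, `dose`,
#' `coupling_time`).
#'
#' @param plan a [SynthesisPlan-class].
#' @param dir output directory (created if needed).
#' @param ascii write P1 masks instead of P4.
#' @return `readCycleManifest()` the manifest data.frame; the writer
#'   returns the manifest path invisibly.
#' @export
writeSynthesisPlan <- function(plan, dir, ascii = FALSE) {
  stopifnot(is(plan, "SynthesisPlan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cy <- planCycles(plan)
  maskFile <- ifelse(is.na(cy$mask), "FLOOD", paste0(cy$mask, ".pbm"))
  for (i in which(!is.na(cy$mask)))
    writePBM(planMasks(plan)[[cy$mask[i]]],
             file.path(dir, paste0(cy$mask[i], ".pbm")), ascii = ascii)
  manifest <- file.path(dir, "cycles.tsv")
  lines <- c("cycle\tmonomer\tmask_file\tdose\tcoupling_time",
             sprintf("%d\t%s\t%s\t%s\t%s", cy$cycle, cy$monomer, maskFile,
                     .fmtNum(cy$dose), .fmtNum(cy$coupling_time)))
  .writeLines(lines, manifest)
  invisible(manifest)
}

#' @param path manifest file.
#' @rdname writeSynthesisPlan
#' @export
readCycleManifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cycle", "monomer", "mask_file", "dose", "coupling_time")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("readCycleManifest: missing column(s): %s",
                 paste(miss, collapse = ", ")))
  d
}

#' YAML run configuration
#'
#' Structured configuration (platform, primer, seed, replicate count,
#' ...) for the command-line workflow.
#'
#' @param config named list.
#' @param path file path.
#' @return `readConfig()` the named list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Write a quantification report
#'
#' Tab-delimited per-probe statistics plus a JSON summary.
#'
#' @param stats [aggregateScan()] output.
#' @param path TSV path; the JSON summary lands at `paste0(path, ".json")`.
#' @param summary named list of summary quantities for the JSON file.
#' @return The TSV path, invisibly.
#' @export
writeQuantReport <- function(stats, path, summary = list()) {
  d <- stats[, c("probe_id", "channel", "n", "mean", "sd", "n_excluded")]
  lines <- c(paste(names(d), collapse = "\t"),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(d$probe_id[i], d$channel[i], d$n[i],
                       .fmtNum(d$mean[i]),
                       ifelse(is.na(d$sd[i]), "NA", .fmtNum(d$sd[i])),
                       d$n_excluded[i]), collapse = "\t"), character(1)))
  .writeLines(lines, path)
  if (length(summary) > 0)
    jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
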