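# Strand arithmetic for the chimeric-oligo model. All sequences are 5'->3'.

.revString <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Re-express a sequence in another chemistry
#'
#' Translates T<->U as needed; U and T are distinct characters and are
#' never compared implicitly across chemistries.
#'
#' @param seq sequence string(s), 5'->3'.
#' @param from,to chemistries (`"DNA"`, `"RNA"`, `"OMe"`).
#' @return The sequence in the target alphabet.
#' @examples
#' chemConvert("UAGGGACACGGCGAA", "OMe", "DNA")
#' @export
chemConvert <- function(seq, from, to) {
  stopifnot(from %in% CHEMISTRIES, to %in% CHEMISTRIES)
  for (i in seq_along(seq)) {
    msg <- .checkAlphabet(seq[i], from)
    if (!is.null(msg)) stop("chemConvert: ", msg)
  }
  fromDNA <- from == "DNA"
  toDNA <- to == "DNA"
  if (fromDNA && !toDNA) chartr("T", "U", seq)
  else if (!fromDNA && toDNA) chartr("U", "T", seq)
  else seq
}

#' Chemistry-aware reverse complement
#'
#' Reverse complement of a sequence, re-expressed in the requested output
#' chemistry (T<->U translation happens with the complement, so e.g.
#' `revComp("UAGGGACACGGCGAA", "OMe", "DNA")` yields the DNA
#' primer-complement block `TTCGCCGTGTCCCTA`). Involutive when the
#' chemistries are swapped back.
#'
#' @param seq sequence string(s), 5'->3'.
#' @param inChem chemistry of `seq`.
#' @param outChem chemistry of the result (defaults to `inChem`).
#' @return Reverse complement string(s), 5'->3', in `outChem`.
#' @examples
#' revComp("UAGGGACACGGCGAA", "OMe", "DNA")  # TTCGCCGTGTCCCTA
#' revComp("A", "DNA")                       # T
#' @export
revComp <- function(seq, inChem = "DNA", outChem = inChem) {
  stopifnot(inChem %in% CHEMISTRIES, outChem %in% CHEMISTRIES)
  for (i in seq_along(seq)) {
    msg <- .checkAlphabet(seq[i], inChem)
    if (!is.null(msg))
      stop(sprintf("revComp: %s (sequence %d)", msg, i))
  }
  tBase <- if (outChem == "DNA") "T" else "U"
  out <- chartr("ACGTU", paste0("T", "GC", "AA"), seq)  # complement, DNA letters
  if (tBase == "U") out <- chartr("T", "U", out)
  .revString(out)
}

.isWCPair <- function(a, b) {
  # a from an RNA/OMe strand, b DNA (or any): allow A:T, A:U, C:G, G:C, T:A, U:A
  key <- paste0(chartr("U", "T", a), chartr("U", "T", b))
  key %in% c("AT", "TA", "CG", "GC")
}

#' Predicted primer-extension product of a template
#'
#' Models T7 RNA polymerase extension of the photocrosslinked 2'-OMe
#' primer along a transcribable template: the product is the primer
#' segment followed by an RNA segment equal to the reverse complement of
#' the template's variable region, carrying the 5' psoralen.
#'
#' @param template a transcribable [TemplateSpec-class].
#' @param primer the [PrimerSpec-class] hybridized to the template's
#'   primer-complement block.
#' @return A [ChimericOligo-class] (`OMe` primer segment + `RNA` extension
#'   segment, `label5 = "psoralen"`).
#' @examples
#' tpl <- makeTemplate("TCAACCCAGGTCCAATTTCC", 5, defaultPrimer())
#' predictedProduct(tpl, defaultPrimer())
#' @export
predictedProduct <- function(template, primer) {
  stopifnot(is(template, "TemplateSpec"), is(primer, "PrimerSpec"))
  if (template@role != "transcribable")
    stop(sprintf("predictedProduct: probe '%s' has role '%s'; only transcribable templates are extended",
                 template@probeId, template@role))
  if (nchar(template@variable) == 0)
    stop("predictedProduct: empty variable region, nothing to transcribe")
  pseq <- oligoSequence(primer)
  plen <- nchar(pseq)
  full <- template@fullSequence
  vlen <- nchar(template@variable)
  if (nchar(full) < vlen + plen)
    stop("predictedProduct: template too short to carry the primer-complement block")
  block <- substr(full, vlen + 1, vlen + plen)
  expected <- revComp(pseq, "OMe", "DNA")
  if (block != expected) {
    bs <- strsplit(block, "")[[1]]; es <- strsplit(expected, "")[[1]]
    mism <- which(bs != es)
    stop(sprintf("predictedProduct: primer/template mismatch at block position(s) %s",
                 paste(mism, collapse = ", ")))
  }
  chimericOligo(c(pseq, revComp(template@variable, "DNA", "RNA")),
                c("OMe", "RNA"), label5 = "psoralen")
}

#' Assemble a solution-phase reference template
#'
#' Builds the DNA strand used to replicate the array conversion in
#' solution: 5'->3' it is the variable (template) region, then the
#' complement of the primer, then a dT 5mer standing in for the surface
#' linker. With a 30 nt variable region and a 27 nt primer this is the
#' 62 nt reference species whose full-length extension product (primer +
#' 30 nt RNA) runs at 57 nt.
#'
#' @param variable variable region, DNA 5'->3' (30 nt in the reference
#'   design; any non-empty length is accepted).
#' @param primer a [PrimerSpec-class] or single-segment OMe
#'   [ChimericOligo-class] (27 nt in the reference design).
#' @return A single-segment DNA [ChimericOligo-class].
#' @examples
#' p27 <- primerSpec(paste0(strrep("ACGU", 6), "ACG"), "sol27")
#' oligoLength(assembleSolutionTemplate(strrep("ACGTGA", 5), p27))  # 62
#' @export
assembleSolutionTemplate <- function(variable, primer) {
  if (is(primer, "PrimerSpec")) primer <- primer@oligo
  stopifnot(is(primer, "ChimericOligo"))
  seg <- oligoSegments(primer)
  if (nrow(seg) != 1 || seg$chem != "OMe")
    stop("assembleSolutionTemplate: primer must be a single 2'-OMe segment")
  if (length(variable) != 1 || nchar(variable) == 0)
    stop("assembleSolutionTemplate: variable region must be non-empty")
  msg <- .checkAlphabet(variable, "DNA")
  if (!is.null(msg)) stop("assembleSolutionTemplate: ", msg)
  full <- paste0(variable, revComp(seg$seq, "OMe", "DNA"), strrep("T", 5))
  chimericOligo(full, "DNA")
}
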