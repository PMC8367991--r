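#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width reduce setdiff findOverlaps
NULL

## ---------------------------------------------------------------------------
## TranscriptModel / GeneModel: one annotated gene with its isoforms.
## Coordinates are genomic, 1-based inclusive (GFF3 convention), strand-aware
## ordering is applied only when sequence is extracted.
## ---------------------------------------------------------------------------

#' TranscriptModel: a single transcript isoform
#'
#' Holds the exon and CDS intervals of one isoform (genomic, 1-based
#' inclusive), the derived UTR intervals, and the translated protein.
#' Protein-only inputs (no coordinates) leave the interval slots empty.
#'
#' @slot transcriptId character, unique within the gene.
#' @slot exons [IRanges::IRanges] of exon intervals.
#' @slot cds [IRanges::IRanges] of coding intervals.
#' @slot utr5,utr3 derived UTR intervals (empty if no coordinates).
#' @slot protein single amino-acid string (stop removed); `NA` if non-coding.
#' @slot status one of `"ok"`, `"noncoding"`, `"malformed"`.
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    exons        = "IRanges",
    cds          = "IRanges",
    utr5         = "IRanges",
    utr3         = "IRanges",
    protein      = "character",
    status       = "character"
  ),
  prototype(
    exons = IRanges::IRanges(), cds = IRanges::IRanges(),
    utr5 = IRanges::IRanges(), utr3 = IRanges::IRanges(),
    protein = NA_character_, status = "ok"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (length(object@transcriptId) != 1L || is.na(object@transcriptId))
    msg <- c(msg, "transcriptId must be a single string")
  if (!object@status %in% c("ok", "noncoding", "malformed"))
    msg <- c(msg, "invalid status")
  if (length(object@cds) > 0L && length(object@exons) > 0L) {
    ## CDS must sit inside exon coverage
    notin <- IRanges::setdiff(IRanges::reduce(object@cds),
                              IRanges::reduce(object@exons))
    if (length(notin) > 0L)
      msg <- c(msg, "CDS intervals extend outside exon coverage")
  }
  if (object@status == "ok" && !is.na(object@protein) &&
      grepl("\\*", object@protein))
    msg <- c(msg, "protein contains an internal stop")
  if (length(msg)) msg else TRUE
})

#' GeneModel: a gene with its transcript isoforms
#'
#' @slot geneId character, unique within a species.
#' @slot species character species tag.
#' @slot chromosome character sequence name (`"ChrUn"` pools unplaced
#'   scaffolds in reports, but the original name is kept here).
#' @slot strand `"+"` or `"-"` (single value for all isoforms).
#' @slot placed logical; `FALSE` for genes on unassigned scaffolds.
#' @slot transcripts list of [TranscriptModel-class] objects.
#' @export
setClass("GeneModel",
  representation(
    geneId      = "character",
    species     = "character",
    chromosome  = "character",
    strand      = "character",
    placed      = "logical",
    transcripts = "list"
  ),
  prototype(strand = "+", placed = TRUE, transcripts = list())
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (!all(vapply(object@transcripts, is, logical(1), "TranscriptModel")))
    msg <- c(msg, "transcripts must all be TranscriptModel objects")
  ids <- vapply(object@transcripts, function(t) t@transcriptId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate transcript id: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ",")))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DomainProfile: position-specific log-odds model of the zinc-finger domain,
## used to call partial (IV_p) domains that lack the complete cysteine tetrad.
## ---------------------------------------------------------------------------

#' DomainProfile: log-odds profile for partial-domain calling
#'
#' @slot logOdds numeric matrix, positions x 20 residues (columns in
#'   alphabetical one-letter order).
#' @slot background length-20 background residue frequencies of the
#'   reference set.
#' @slot threshold minimum window score for an IV_p call.
#' @export
setClass("DomainProfile",
  representation(logOdds = "matrix", background = "numeric",
                 threshold = "numeric"))

setValidity("DomainProfile", function(object) {
  msg <- character()
  if (ncol(object@logOdds) != 20L || !identical(colnames(object@logOdds), AA20))
    msg <- c(msg, "logOdds must have the 20 standard residues as columns")
  if (length(object@background) != 20L)
    msg <- c(msg, "background must have 20 entries")
  ## each position's background-weighted exponentiated scores are a
  ## probability distribution
  norm <- as.vector(exp(object@logOdds) %*% object@background)
  if (any(abs(norm - 1) > 1e-9))
    msg <- c(msg, "profile positions do not normalize against the background")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DomainAlignment: cysteine-anchored alignment of complete domains.
## ---------------------------------------------------------------------------

#' DomainAlignment: cysteine-anchored domain alignment
#'
#' Rows are gapped domain sequences of equal width; the four anchor columns
#' hold the C1--C4 cysteines (or an end-gap for rows whose flanks were
#' shorter than requested).
#'
#' @slot rows named character vector of aligned strings.
#' @slot anchorColumns integer(4), 1-based columns of C1--C4.
#' @export
setClass("DomainAlignment",
  representation(rows = "character", anchorColumns = "integer"))

setValidity("DomainAlignment", function(object) {
  msg <- character()
  if (length(object@rows) == 0L) msg <- c(msg, "alignment has no rows")
  w <- unique(nchar(object@rows))
  if (length(w) > 1L) msg <- c(msg, "rows differ in width")
  if (length(object@anchorColumns) != 4L)
    msg <- c(msg, "anchorColumns must have length 4")
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
    msg <- c(msg, "rows must carry unique member names")
  if (length(msg) == 0L) {
    m <- alignmentMatrix(object)
    anch <- m[, object@anchorColumns, drop = FALSE]
    if (!all(anch %in% c("C", "-")))
      msg <- c(msg, "anchor columns must contain only C or gap")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GeneCluster: one multi-species clade of family members (a "PC").
## ---------------------------------------------------------------------------

#' GeneCluster: a supported multi-species clade of family members
#'
#' @slot pcId character label (`"PC01"`, ...).
#' @slot members character member (TF) identifiers.
#' @slot speciesCounts named integer, members per species.
#' @slot support bootstrap support percentage of the defining edge.
#' @slot subfamily subfamily label of the clade.
#' @export
setClass("GeneCluster",
  representation(pcId = "character", members = "character",
                 speciesCounts = "integer", support = "numeric",
                 subfamily = "character"))

setValidity("GeneCluster", function(object) {
  msg <- character()
  if (length(object@members) < 2L)
    msg <- c(msg, "a cluster needs at least 2 members")
  if (sum(object@speciesCounts) != length(object@members))
    msg <- c(msg, "speciesCounts must sum to the member count")
  if (length(msg)) msg else TRUE
})

## ------------------------------- accessors --------------------------------

#' @describeIn GeneModel-class gene identifier
#' @param object a GeneModel/TranscriptModel/DomainAlignment object.
#' @export
geneId <- function(object) object@geneId

#' @describeIn GeneModel-class species tag
#' @export
geneSpecies <- function(object) object@species

#' @describeIn GeneModel-class chromosome / scaffold name
#' @export
geneChromosome <- function(object) object@chromosome

#' @describeIn GeneModel-class strand
#' @export
geneStrand <- function(object) object@strand

#' @describeIn GeneModel-class placement flag
#' @export
genePlaced <- function(object) object@placed

#' @describeIn GeneModel-class list of transcripts
#' @export
transcripts <- function(object) object@transcripts

#' Coding transcripts of a gene
#'
#' Transcripts with a translated protein and `status == "ok"`; malformed and
#' non-coding isoforms are excluded from all downstream family analyses.
#' @param gene a [GeneModel-class].
#' @return list of [TranscriptModel-class].
#' @export
codingTranscripts <- function(gene) {
  Filter(function(t) t@status == "ok" && !is.na(t@protein), gene@transcripts)
}

#' @describeIn TranscriptModel-class transcript identifier
#' @param object object.
#' @export
transcriptId <- function(object) object@transcriptId

#' @describeIn TranscriptModel-class exon intervals
#' @export
exonRanges <- function(object) object@exons

#' @describeIn TranscriptModel-class CDS intervals
#' @export
cdsRanges <- function(object) object@cds

#' @describeIn TranscriptModel-class translated protein (stop removed)
#' @export
proteinSequence <- function(object) object@protein

#' @describeIn DomainAlignment-class aligned rows (named character vector)
#' @export
alignedRows <- function(object) object@rows

#' @describeIn DomainAlignment-class anchor (cysteine) column indices
#' @export
anchorColumns <- function(object) object@anchorColumns

#' @describeIn DomainAlignment-class alignment as a character matrix
#' @export
alignmentMatrix <- function(object) {
  m <- do.call(rbind, strsplit(object@rows, ""))
  rownames(m) <- names(object@rows)
  m
}

#' @describeIn GeneCluster-class cluster id
#' @export
pcId <- function(object) object@pcId

#' @describeIn GeneCluster-class member ids
#' @export
clusterMembers <- function(object) object@members

#' @describeIn GeneCluster-class per-species member counts
#' @export
speciesCounts <- function(object) object@speciesCounts

#' @describeIn GeneCluster-class bootstrap support of the defining edge
#' @export
clusterSupport <- function(object) object@support

#' @describeIn GeneCluster-class subfamily label
#' @export
clusterSubfamily <- function(object) object@subfamily

## ------------------------------- show -------------------------------------

setMethod("show", "GeneModel", function(object) {
  n <- length(object@transcripts)
  nc <- length(codingTranscripts(object))
  cat("GeneModel", object@geneId, "(", object@species, ")",
      object@chromosome, object@strand,
      if (!object@placed) "[unplaced]" else "", "\n")
  cat("  ", n, "transcript(s),", nc, "coding\n")
})

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("[%s] %d exon(s), %d CDS segment(s)", object@status,
              length(object@exons), length(object@cds)), "\n")
  if (!is.na(object@protein))
    cat("  protein:", nchar(object@protein), "aa\n")
})

setMethod("show", "DomainProfile", function(object) {
  cat("DomainProfile:", nrow(object@logOdds), "positions, threshold",
      signif(object@threshold, 4), "\n")
})

setMethod("show", "DomainAlignment", function(object) {
  cat("DomainAlignment:", length(object@rows), "rows x",
      nchar(object@rows[[1]]), "columns; anchors at",
      paste(object@anchorColumns, collapse = ","), "\n")
})

setMethod("show", "GeneCluster", function(object) {
  cat(object@pcId, "(subfamily", object@subfamily, "):",
      length(object@members), "members across",
      length(object@speciesCounts), "species; support",
      object@support, "\n")
})
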