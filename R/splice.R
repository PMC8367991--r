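## ---------------------------------------------------------------------------
## splice_analysis: per-gene classification of alternative-splicing forms and
## the family-level splicing summary arithmetic.
## ---------------------------------------------------------------------------

#' Classify the splice forms of one gene
#'
#' The canonical isoform is the longest protein (ties broken by
#' lexicographic transcript id). Every other coding isoform is labelled:
#' \describe{
#'   \item{identical_protein}{protein string equals the canonical protein;
#'     if additionally the CDS intervals equal the canonical's while the
#'     exon set differs, the `utr_only` flag is set (the splice change is
#'     confined to untranslated regions).}
#'   \item{utr_only_variant}{CDS interval set equals the canonical's but the
#'     exon set differs, with a protein that differs (possible only through
#'     annotation quirks); requires coordinates.}
#'   \item{domain_loss}{the canonical has at least one zinc-finger domain
#'     and this isoform has none — a putative negative-regulator form.}
#'   \item{other}{anything else.}
#' }
#' `domain_loss` takes precedence over `other`; `identical_protein` over
#' `utr_only_variant`. On coordinate-free models (protein FASTA input) the
#' UTR-only call is unavailable and `utr_only_available` is `FALSE`.
#'
#' @param gene a [GeneModel-class] with at least one coding isoform.
#' @param hits named list of per-isoform hit data.frames
#'   (from [scanFamily()]).
#' @return list with `gene_id`, `n_isoforms` (coding), `canonical`,
#'   `categories` (named character), `utr_only_flags` (named logical),
#'   `n_domain_bearing`, `utr_only_available`.
#' @export
classifyIsoforms <- function(gene, hits) {
  txs <- codingTranscripts(gene)
  if (!length(txs)) stop("gene ", gene@geneId, " has no coding isoform")
  ids <- vapply(txs, transcriptId, character(1))
  prots <- vapply(txs, proteinSequence, character(1))
  names(prots) <- ids
  hasCoords <- any(vapply(txs, function(t) length(t@exons) > 0L, logical(1)))

  canon <- ids[order(-nchar(prots), ids)][1]
  canonTx <- txs[[match(canon, ids)]]
  canonHits <- hits[[canon]]
  canonBearing <- !is.null(canonHits) && isDomainBearing(canonHits)

  cats <- setNames(rep("canonical", length(ids)), ids)
  utrFlags <- setNames(rep(FALSE, length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id == canon) next
    tx <- txs[[i]]
    sameCds <- hasCoords && identical(asIntervalKey(tx@cds),
                                      asIntervalKey(canonTx@cds))
    diffExons <- hasCoords && !identical(asIntervalKey(tx@exons),
                                         asIntervalKey(canonTx@exons))
    bearing <- !is.null(hits[[id]]) && isDomainBearing(hits[[id]])
    if (prots[[id]] == prots[[canon]]) {
      cats[id] <- "identical_protein"
      utrFlags[id] <- sameCds && diffExons
    } else if (sameCds && diffExons) {
      cats[id] <- "utr_only_variant"
    } else if (canonBearing && !bearing) {
      cats[id] <- "domain_loss"
    } else {
      cats[id] <- "other"
    }
  }
  nBearing <- sum(vapply(ids, function(id)
    !is.null(hits[[id]]) && isDomainBearing(hits[[id]]), logical(1)))
  list(gene_id = gene@geneId, n_isoforms = length(ids), canonical = canon,
       categories = cats, utr_only_flags = utrFlags,
       n_domain_bearing = nBearing, utr_only_available = hasCoords)
}

asIntervalKey <- function(r) {
  paste(sort(paste(IRanges::start(r), IRanges::end(r), sep = "-")),
        collapse = ";")
}

#' Family membership of genes
#'
#' A gene belongs to the family iff at least one of its coding isoforms
#' carries a domain hit; its domain-less isoforms still count as the
#' member's splice forms (flagged by [classifyIsoforms()]), but genes whose
#' isoforms all lack the domain are excluded outright.
#'
#' @param genes list of [GeneModel-class].
#' @param hits named list of per-isoform hits.
#' @param includePartial count IV_p-only isoforms as domain-bearing.
#' @return logical vector along `genes`.
#' @export
isFamilyMember <- function(genes, hits, includePartial = TRUE) {
  vapply(genes, function(g) {
    any(vapply(codingTranscripts(g), function(t) {
      h <- hits[[t@transcriptId]]
      !is.null(h) && isDomainBearing(h, includePartial)
    }, logical(1)))
  }, logical(1))
}

#' Per-species alternative-splicing summary
#'
#' Computes, over the domain-bearing (member) genes of one species:
#' A = member gene count, TF count (coding isoforms of members),
#' B = members with >= 2 coding isoforms, TFs belonging to those genes,
#' `ratio = 100 B / A` and `avg_forms` = (isoforms carried by AS genes)/B,
#' both half-up rounded to 2 decimals. `avg_forms` is `NA` when B = 0.
#'
#' @param genes list of [GeneModel-class] from one species.
#' @param hits named per-isoform hit list.
#' @return one-row data.frame with columns `species, A, n_tf, B, n_tf_as,
#'   ratio, avg_forms`.
#' @export
speciesSpliceSummary <- function(genes, hits) {
  member <- isFamilyMember(genes, hits)
  fam <- genes[member]
  if (!length(fam)) stop("no family members for species")
  sp <- fam[[1]]@species
  iso <- vapply(fam, function(g) length(codingTranscripts(g)), integer(1))
  A <- length(fam)
  B <- sum(iso >= 2L)
  data.frame(species = sp, A = A, n_tf = sum(iso), B = B,
             n_tf_as = sum(iso[iso >= 2L]),
             ratio = asRatio(A, B),
             avg_forms = avgSpliceForms(sum(iso[iso >= 2L]), B),
             stringsAsFactors = FALSE)
}

#' Average number of splice forms per alternatively-spliced gene
#'
#' @param totalForms total isoforms carried by the genes with >= 2 forms.
#' @param B number of genes with >= 2 forms.
#' @return `totalForms / B` half-up rounded to 2 decimals; `NA` if `B` is 0.
#' @export
avgSpliceForms <- function(totalForms, B) {
  if (B <= 0) return(NA_real_)
  roundHalfUp(totalForms / B)
}

#' Alternative-splicing ratio B/A as a percentage
#'
#' @param A member gene count.
#' @param B members with alternative-splicing forms.
#' @return `100 * B / A`, half-up rounded to 2 decimals.
#' @export
asRatio <- function(A, B) {
  if (A <= 0) stop("no family members (A = 0)")
  roundHalfUp(100 * B / A)
}

#' Genus-level alternative-splicing ratio with an excluded denominator
#'
#' Sums B over all species but A only over the non-excluded ones — the
#' arithmetic used when a species without any splice forms is dropped from
#' the denominator of the genus total.
#'
#' @param summaries data.frame with `species`, `A`, `B` columns
#'   (e.g. rbind of [speciesSpliceSummary()] rows).
#' @param exclude character vector of species removed from the denominator.
#' @return percentage, half-up rounded to 2 decimals.
#' @export
genusSpliceRatio <- function(summaries, exclude = character()) {
  keep <- !(summaries$species %in% exclude)
  if (!any(keep)) stop("all species excluded from the denominator")
  denom <- sum(summaries$A[keep])
  if (denom == 0) stop("zero denominator")
  roundHalfUp(100 * sum(summaries$B) / denom)
}
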