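## ---------------------------------------------------------------------------
## family_stats: census tables -- per-species family summary, domain-type
## census at the TF (isoform) level, PC evenness, chromosomal distribution,
## species-level PCA of family characteristics.
## ---------------------------------------------------------------------------

#' Per-species family summary table
#'
#' One row per species: member gene count (A), TF count (coding isoforms of
#' members), genes/TFs with alternative-splicing forms, the B/A percentage
#' and the family's proportion of all genes in the genome (when genome
#' totals are supplied; otherwise that column is omitted with a warning).
#'
#' @param genesBySpecies named list (species -> list of
#'   [GeneModel-class]).
#' @param hits named per-isoform hit list covering all species.
#' @param genomeTotals optional named numeric: species -> total gene count
#'   of the genome (the family proportion denominator).
#' @return data.frame with one row per species plus a `Total` row; the
#'   total's `ratio` uses the plain pooled denominator (use
#'   [genusSpliceRatio()] for an excluded-denominator total).
#' @export
familySummary <- function(genesBySpecies, hits, genomeTotals = NULL) {
  rows <- lapply(genesBySpecies, speciesSpliceSummary, hits = hits)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(genomeTotals)) {
    tab$genome_genes <- as.numeric(genomeTotals[tab$species])
    tab$proportion <- familyProportion(tab$A, tab$genome_genes)
  } else {
    warning("genome gene totals not supplied; proportion column omitted")
  }
  total <- data.frame(species = "Total", A = sum(tab$A),
                      n_tf = sum(tab$n_tf), B = sum(tab$B),
                      n_tf_as = sum(tab$n_tf_as),
                      ratio = asRatio(sum(tab$A), sum(tab$B)),
                      avg_forms = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(genomeTotals)) {
    total$genome_genes <- sum(tab$genome_genes)
    total$proportion <- familyProportion(total$A, total$genome_genes)
  }
  rbind(tab, total)
}

#' Family share of all genes in a genome
#'
#' @param nFamilyGenes member gene count.
#' @param genomeTotal total genes in the genome annotation.
#' @return percentage, half-up rounded to 2 decimals.
#' @export
familyProportion <- function(nFamilyGenes, genomeTotal) {
  roundHalfUp(100 * nFamilyGenes / genomeTotal)
}

#' Representative domain type of each TF
#'
#' One type per coding isoform: the type of its best-scoring hit (pattern
#' hits outrank profile-only IV_p calls; among pattern hits the first in
#' position order is used).
#'
#' @param hits named per-isoform hit list.
#' @return named character vector (isoform -> type); isoforms without hits
#'   are dropped.
#' @export
representativeTypes <- function(hits) {
  out <- character()
  for (id in names(hits)) {
    h <- hits[[id]]
    if (is.null(h) || !nrow(h)) next
    complete <- h[h$type != "IV_p", , drop = FALSE]
    out[id] <- if (nrow(complete)) complete$type[1]
               else h$type[which.max(h$score)]
  }
  out
}

#' Domain-type census over the family's TFs
#'
#' Counts and percentages (half-up, 2 decimals) of each representative
#' domain type over all TFs.
#'
#' @param types named character vector from [representativeTypes()], or any
#'   character vector of per-TF type labels.
#' @return data.frame `type`, `count`, `percentage`, sorted by descending
#'   count.
#' @export
domainTypeCensus <- function(types) {
  if (!length(types)) stop("no TFs to census")
  tab <- sort(table(types), decreasing = TRUE)
  data.frame(type = names(tab), count = as.integer(tab),
             percentage = roundHalfUp(100 * as.integer(tab) / length(types)),
             stringsAsFactors = FALSE)
}

#' Evenness of gene clusters across species
#'
#' A cluster is even iff it contains every analysed species and all its
#' per-species member counts are equal. Clusters missing a species (like a
#' 5-of-7 cluster) are uneven regardless of balance.
#'
#' @param clusters list of [GeneCluster-class].
#' @param allSpecies character vector of analysed species.
#' @return list `(n_even, n_total, percentage)`.
#' @export
pcEvenness <- function(clusters, allSpecies) {
  if (!length(clusters)) stop("no clusters")
  even <- vapply(clusters, function(cl) {
    sc <- speciesCounts(cl)
    setequal(names(sc), allSpecies) && length(unique(sc)) == 1L
  }, logical(1))
  list(n_even = sum(even), n_total = length(clusters),
       percentage = roundHalfUp(100 * sum(even) / length(clusters)))
}

#' Chromosomal distribution of family genes
#'
#' Counts per chromosome with unplaced genes pooled as `"ChrUn"`, and gene
#' density per Mb when chromosome lengths are available.
#'
#' @param genes list of [GeneModel-class] (one species).
#' @param chromosomeLengths optional named numeric of chromosome lengths in
#'   bases.
#' @return data.frame `chromosome`, `count`, `length_bp`, `density_per_mb`;
#'   attribute `"extremes"` names the max/min density chromosomes.
#' @export
chromosomeDistribution <- function(genes, chromosomeLengths = NULL) {
  chrom <- vapply(genes, function(g)
    if (genePlaced(g)) geneChromosome(g) else "ChrUn", character(1))
  if (!is.null(chromosomeLengths)) {
    bad <- setdiff(setdiff(unique(chrom), "ChrUn"), names(chromosomeLengths))
    if (length(bad))
      stop("placed gene(s) on unknown chromosome: ",
           paste(bad, collapse = ","))
    lv <- c(sort(names(chromosomeLengths)), "ChrUn")
  } else lv <- c(sort(setdiff(unique(chrom), "ChrUn")), "ChrUn")
  cnt <- table(factor(chrom, levels = lv))
  out <- data.frame(chromosome = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  if (!is.null(chromosomeLengths)) {
    out$length_bp <- as.numeric(chromosomeLengths[out$chromosome])
    out$density_per_mb <- ifelse(is.na(out$length_bp) | out$length_bp == 0, 0,
                                 out$count / (out$length_bp / 1e6))
    placed <- out[out$chromosome != "ChrUn" & out$count > 0, , drop = FALSE]
    if (nrow(placed))
      attr(out, "extremes") <- list(
        max_density = placed$chromosome[which.max(placed$density_per_mb)],
        min_density = placed$chromosome[which.min(placed$density_per_mb)],
        max_count = placed$chromosome[which.max(placed$count)])
  }
  out
}

#' Species-level feature table for the family PCA
#'
#' A documented default set of 19 species-level characteristics of the
#' family: gene/TF counts, AS ratio, mean/median protein length, mean exon
#' and isoform counts, domain-type fractions (5), subfamily fractions (4),
#' mean relative domain start, ChrUn fraction and mean basic-region
#' fraction. Intended as input for [speciesFeaturePCA()].
#'
#' @param genesBySpecies named list (species -> list of gene models).
#' @param hits named per-isoform hit list.
#' @param subfamilies optional named character vector (member -> subfamily).
#' @return numeric matrix, species x 19 features.
#' @export
speciesFeatureTable <- function(genesBySpecies, hits, subfamilies = NULL) {
  feat <- lapply(names(genesBySpecies), function(sp) {
    genes <- genesBySpecies[[sp]]
    member <- isFamilyMember(genes, hits)
    fam <- genes[member]
    prots <- familyProteins(fam)
    types <- representativeTypes(hits[names(hits) %in% names(prots)])
    iso <- vapply(fam, function(g) length(codingTranscripts(g)), integer(1))
    exn <- unlist(lapply(fam, function(g)
      vapply(codingTranscripts(g), function(t)
        max(1L, length(t@exons)), integer(1))))
    relStart <- basics <- numeric()
    for (id in names(prots)) {
      h <- hits[[id]]
      if (is.null(h) || !nrow(h)) next
      relStart <- c(relStart, h$start[1] / nchar(prots[[id]]))
      basics <- c(basics, h$basic_fraction[1])
    }
    sfFrac <- function(lab) {
      if (is.null(subfamilies)) return(NA_real_)
      s <- subfamilies[names(subfamilies) %in% names(prots)]
      if (!length(s)) return(0) else mean(s == lab)
    }
    tfrac <- function(lab) if (length(types)) mean(types == lab) else 0
    c(n_genes = length(fam), n_tf = sum(iso),
      as_ratio = asRatio(length(fam), sum(iso >= 2L)),
      mean_protein_len = mean(nchar(prots)),
      median_protein_len = stats::median(nchar(prots)),
      mean_exons = mean(exn), mean_isoforms = mean(iso),
      frac_iva = tfrac("IV_a"), frac_ivb = tfrac("IV_b"),
      frac_ivc = tfrac("IV_c"), frac_iv4 = tfrac("IV_4"),
      frac_ivp = tfrac("IV_p"),
      frac_sfI = sfFrac("I"), frac_sfII = sfFrac("II"),
      frac_sfIII = sfFrac("III"), frac_sfIV = sfFrac("IV"),
      mean_domain_start = mean(relStart),
      chrun_fraction = mean(!vapply(fam, genePlaced, logical(1))),
      mean_basic_fraction = mean(basics, na.rm = TRUE))
  })
  out <- do.call(rbind, feat)
  rownames(out) <- names(genesBySpecies)
  out
}

#' PCA of species-level family characteristics
#'
#' Standardizes the features (zero mean, unit variance; constant features
#' are dropped with a warning), decomposes, and returns the first two
#' component coordinates and the variance fractions. Sign convention: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param featureTable numeric matrix, species x features (>= 3 species,
#'   >= 2 informative features).
#' @return list with `coordinates` (species x 2), `variance_fractions`
#'   (all components), `loadings`.
#' @export
speciesFeaturePCA <- function(featureTable) {
  x <- as.matrix(featureTable)
  if (nrow(x) < 3L) stop("need at least 3 species")
  keep <- apply(x, 2, function(col)
    !anyNA(col) && stats::sd(col) > .Machine$double.eps^0.5)
  if (any(!keep))
    warning("dropping constant/NA feature(s): ",
            paste(colnames(x)[!keep], collapse = ","))
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 informative features")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = scores[, 1:2, drop = FALSE],
       variance_fractions = vf, loadings = rot)
}
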