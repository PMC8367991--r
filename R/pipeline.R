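## ---------------------------------------------------------------------------
## cli_report: one entry point running the stage chain
## scan -> splice -> align/phylo -> clusters -> conservation -> stats ->
## expression -> tmh, writing every table plus a headline summary.
## ---------------------------------------------------------------------------

#' Run the whole family-analysis pipeline
#'
#' @param config either a YAML file path or a list with entries:
#'   \describe{
#'     \item{species}{named list; each element either
#'       `list(gff3 =, fasta =)` or `list(proteins =)` (protein FASTA).}
#'     \item{anchors}{optional: `list(fasta =, subfamilies =)` where
#'       `subfamilies` is a TSV path (`anchor_id`, `subfamily`) or a named
#'       vector.}
#'     \item{expression}{optional FPKM CSV/TSV path or matrix.}
#'     \item{genome_totals}{optional named vector of genome gene counts.}
#'     \item{seed, bootstrap, min_species, min_support, exclude_species,
#'       flank5, flank3}{tuning knobs with the package defaults.}
#'   }
#' @param outDir directory for the report bundle (created). `NULL` skips
#'   writing and returns results in memory only.
#' @return list with the stage results: `genesBySpecies`, `hits`, `summary`
#'   (family table), `tree`, `subfamilies`, `clusters`, `patterns`,
#'   `census`, `evenness`, `coherence` (if expression given), `tmh`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$species) || !length(config$species))
    stop("config must name at least one species input")
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    paths <- unlist(s[intersect(names(s), c("gff3", "fasta", "proteins"))])
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stop("missing input file(s) for ", sp, ": ",
           paste(miss, collapse = ","))
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  boot <- if (is.null(config$bootstrap)) 100L else as.integer(config$bootstrap)
  minSpecies <- if (is.null(config$min_species)) 5L else
    as.integer(config$min_species)
  minSupport <- if (is.null(config$min_support)) 50 else config$min_support
  flank5 <- if (is.null(config$flank5)) 7L else as.integer(config$flank5)
  flank3 <- if (is.null(config$flank3)) 25L else as.integer(config$flank3)

  ## stage 1: ingest
  genesBySpecies <- lapply(names(config$species), function(sp) {
    s <- config$species[[sp]]
    if (!is.null(s$gff3)) readGenomeAnnotation(s$gff3, s$fasta, species = sp)
    else readProteome(s$proteins, species = sp)
  })
  names(genesBySpecies) <- names(config$species)

  ## stage 2: scan
  allGenes <- unlist(genesBySpecies, recursive = FALSE)
  hits <- scanFamily(allGenes)

  ## stage 3: splice summary
  summary <- familySummary(genesBySpecies, hits,
                           genomeTotals = config$genome_totals)
  genusRatio <- genusSpliceRatio(
    summary[summary$species != "Total", ],
    exclude = if (is.null(config$exclude_species)) character() else
      config$exclude_species)

  ## stage 4: align + tree over the TFs' best complete domains (+ anchors)
  member <- isFamilyMember(allGenes, hits)
  famGenes <- allGenes[member]
  famProts <- familyProteins(famGenes)
  best <- bestCompleteHits(hits[names(hits) %in% names(famProts)])
  anchorMap <- character()
  allProts <- famProts
  if (!is.null(config$anchors)) {
    anchorProts <- if (!is.null(config$anchors$proteins_vector))
      config$anchors$proteins_vector
    else {
      aa <- readAAStringSet(config$anchors$fasta)
      stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
    }
    sf <- config$anchors$subfamilies
    if (is.character(sf) && length(sf) == 1L && file.exists(sf)) {
      tab <- utils::read.table(sf, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      sf <- stats::setNames(tab$subfamily, tab$anchor_id)
    }
    anchorMap <- sf
    anchorHits <- scanFamily(lapply(names(anchorProts), function(id) {
      methods::new("GeneModel", geneId = id, species = "anchor",
                   chromosome = "un", strand = "+", placed = FALSE,
                   transcripts = list(methods::new("TranscriptModel",
                     transcriptId = id, protein = anchorProts[[id]],
                     status = "ok")))
    }))
    best <- rbind(best, bestCompleteHits(anchorHits))
    allProts <- c(allProts, anchorProts)
  }
  if (nrow(best) < 3L) stop("phylo stage: fewer than 3 complete domains")
  aln <- anchorAlign(best, allProts, memberIds = best$protein_id,
                     flank5 = flank5, flank3 = flank3)
  tree <- bootstrapSupport(aln, replicates = boot, seed = seed)

  subfamilies <- if (length(anchorMap))
    assignSubfamily(tree, anchorMap) else character()

  ## stage 5: clusters
  speciesOfTf <- tfSpeciesMap(genesBySpecies)
  clusters <- detectClusters(tree,
                             speciesOf = speciesOfTf,
                             minSpecies = min(minSpecies,
                                              length(genesBySpecies)),
                             minSupport = minSupport, anchors = anchorMap)

  ## stage 6: conservation patterns per cluster
  patterns <- lapply(clusters, function(cl)
    groupPattern(aln, intersect(clusterMembers(cl), names(alignedRows(aln))),
                 groupId = pcId(cl)))
  variability <- if (length(patterns)) variabilitySummary(patterns) else NULL

  ## stage 7: stats
  census <- domainTypeCensus(representativeTypes(
    hits[names(hits) %in% names(famProts)]))
  evenness <- if (length(clusters))
    pcEvenness(clusters, names(genesBySpecies)) else NULL

  ## stage 8: expression coherence
  coherence <- NULL
  if (!is.null(config$expression)) {
    m <- if (is.matrix(config$expression)) config$expression else
      readFpkm(config$expression)
    dend <- clusterExpression(m)
    geneOfTf <- tfGeneMap(genesBySpecies)
    clGenes <- lapply(clusters, function(cl)
      unique(stats::na.omit(geneOfTf[clusterMembers(cl)])))
    names(clGenes) <- vapply(clusters, pcId, character(1))
    coherence <- pcCoherence(dend, clGenes)
  }

  ## stage 9: TMH stand-in
  tmh <- scanTmh(famProts)

  res <- list(genesBySpecies = genesBySpecies, hits = hits,
              summary = summary, genus_ratio = genusRatio, alignment = aln,
              tree = tree, subfamilies = subfamilies, clusters = clusters,
              patterns = patterns, variability = variability,
              census = census, evenness = evenness, coherence = coherence,
              tmh = tmh,
              settings = list(seed = seed, bootstrap = boot,
                              min_species = minSpecies,
                              min_support = minSupport))
  if (!is.null(outDir)) writeReportBundle(res, outDir)
  res
}

## best complete hit per isoform (first in position order), as one table
bestCompleteHits <- function(hits) {
  rows <- lapply(hits, function(h) {
    h <- h[h$type != "IV_p", , drop = FALSE]
    if (nrow(h)) h[1, , drop = FALSE] else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) emptyHits() else out
}

tfSpeciesMap <- function(genesBySpecies) {
  out <- character()
  for (sp in names(genesBySpecies))
    for (g in genesBySpecies[[sp]])
      for (t in codingTranscripts(g)) out[transcriptId(t)] <- sp
  out
}

tfGeneMap <- function(genesBySpecies) {
  out <- character()
  for (sp in names(genesBySpecies))
    for (g in genesBySpecies[[sp]])
      for (t in codingTranscripts(g)) out[transcriptId(t)] <- geneId(g)
  out
}

writeReportBundle <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f)
    utils::write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(res$summary, "family_summary.tsv")
  wt(res$census, "domain_type_census.tsv")
  allHits <- do.call(rbind, res$hits)
  if (!is.null(allHits) && nrow(allHits)) wt(allHits, "domain_hits.tsv")
  if (length(res$clusters)) {
    wt(data.frame(
      pc = vapply(res$clusters, pcId, character(1)),
      subfamily = vapply(res$clusters, clusterSubfamily, character(1)),
      support = vapply(res$clusters, clusterSupport, numeric(1)),
      n_members = vapply(res$clusters, function(cl)
        length(clusterMembers(cl)), integer(1)),
      members = vapply(res$clusters, function(cl)
        paste(clusterMembers(cl), collapse = ","), character(1))),
      "clusters.tsv")
  }
  ape::write.tree(res$tree, file.path(outDir, "domain_tree.nwk"))
  writeAlignedFasta(res$alignment, file.path(outDir, "domain_alignment.fa"))
  if (length(res$subfamilies))
    wt(data.frame(member = names(res$subfamilies),
                  subfamily = unname(res$subfamilies)), "subfamilies.tsv")
  if (length(res$patterns))
    wt(data.frame(
      group = vapply(res$patterns, `[[`, character(1), "group_id"),
      pattern = vapply(res$patterns, `[[`, character(1), "pattern"),
      n_variants = vapply(res$patterns, function(p)
        paste(p$n_variants, collapse = ","), character(1))),
      "patterns.tsv")
  if (!is.null(res$coherence))
    wt(data.frame(pc = names(res$coherence),
                  coherence = unname(res$coherence)), "pc_coherence.tsv")
  if (nrow(res$tmh)) wt(res$tmh, "tmh_spans.tsv")

  lines <- c(
    "Family analysis summary",
    "=======================",
    sprintf("Species analysed: %d", nrow(res$summary) - 1L),
    sprintf("Family genes: %d; TFs (coding isoforms): %d",
            res$summary$A[res$summary$species == "Total"],
            res$summary$n_tf[res$summary$species == "Total"]),
    sprintf("Genus AS ratio (excluded denominator): %.2f%%", res$genus_ratio),
    sprintf("Domain-type census: %s",
            paste(sprintf("%s %d (%.2f%%)", res$census$type,
                          res$census$count, res$census$percentage),
                  collapse = "; ")),
    sprintf("Gene clusters detected: %d%s", length(res$clusters),
            if (!is.null(res$evenness))
              sprintf(" (%d even, %.2f%%)", res$evenness$n_even,
                      res$evenness$percentage) else ""),
    if (!is.null(res$variability))
      sprintf("Motif-region variability: %d of %d positions (%.2f%%)",
              res$variability$variable, res$variability$total,
              res$variability$percentage) else NULL,
    sprintf("TMH-bearing isoforms: %d", length(unique(res$tmh$protein_id))),
    sprintf("Settings: seed %d, bootstrap %d, min_species %d, min_support %s",
            res$settings$seed, res$settings$bootstrap,
            res$settings$min_species, res$settings$min_support))
  writeLines(lines, file.path(outDir, "summary.txt"))
  invisible(outDir)
}

#' Write a DomainAlignment as aligned FASTA
#' @param aln [DomainAlignment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(aln, path) {
  rows <- alignedRows(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(rows)) writeLines(c(paste0(">", id), rows[[id]]), con)
  invisible(path)
}

#' Published GATA family census counts for seven poplar genomes
#'
#' The bundled reference table of published family counts across seven
#' annotated *Populus* genomes: member genes (A), TFs, genes/TFs with
#' alternative-splicing forms (B), and genome-wide gene totals. Used for
#' the printed-table arithmetic (AS ratios, genus ratio with an excluded
#' denominator, family proportions).
#'
#' @return data.frame with columns `species`, `A`, `n_tf`, `B`, `n_tf_as`,
#'   `genome_genes`.
#' @export
publishedCensus <- function() {
  path <- system.file("extdata", "populus_gata_census.tsv",
                      package = "gatafam", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
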