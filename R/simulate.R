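## ---------------------------------------------------------------------------
## synthetic_data: seeded generator of multi-species toy genomes with a
## planted GATA family, providing ground truth for every pipeline stage.
##
## The emulated regime: ~7 species, ~21 multi-species orthogroups (a few
## with extra gene copies), ~30% of genes with alternative-splicing forms,
## a small membrane-bound fraction, genes spread over 19 chromosomes with a
## few unplaced scaffolds, and tissue-structured expression for two species.
## ---------------------------------------------------------------------------

## residues allowed in flanking/linker sequence: polar-biased, cysteine-free
## and without strongly hydrophobic letters, so the planted domain keeps the
## only C-tetrad and soluble proteins contain no spurious hydrophobic run.
FLANK_AA <- c("A","D","E","G","H","K","N","P","Q","R","S","T","Y")

## subfamily-diagnostic spacer residues: W/G in subfamilies I, II and IV,
## M/E in subfamily III (two positions inside the second spacer).
subfamilyDomain <- function(subfamily, type) {
  s1 <- if (type == "IV_4") "SNTQ" else "SN"
  d <- if (subfamily == "III") c("M", "E") else c("W", "G")
  s2 <- switch(type,
    IV_a = paste0("TLDGH",   d[1], "AREGKN",   d[2], "QPSD"),
    IV_b = paste0("TLDGHY",  d[1], "AREGKN",   d[2], "QPSD"),
    IV_4 = paste0("TLDGHY",  d[1], "AREGKN",   d[2], "QPSD"),
    IV_c = paste0("TLDGHYSN", d[1], "AREGKN",  d[2], "QPSD"),
    stop("unknown type ", type))
  dom <- paste0("C", s1, "C", s2, "C", "NA", "C")
  cpos <- c(1L, 2L + nchar(s1), 3L + nchar(s1) + nchar(s2),
            6L + nchar(s1) + nchar(s2))
  diagpos <- c(2L + nchar(s1) + regexpr(d[1], s2, fixed = TRUE),
               2L + nchar(s1) + nchar(s2) - 4L)
  list(seq = dom, cpos = cpos, protected = c(cpos, diagpos))
}

#' Synthetic-family generator configuration
#'
#' Defaults describe the emulated genus-scale regime: 7 species, 21
#' orthogroups (one with 4 and two with 2 gene copies per species), four
#' subfamilies with subfamily-III clusters carrying IV_c domains and one
#' subfamily-II cluster carrying IV_4, 5% inter-species drift, ~30% of
#' genes with splice variants, a ~1.3% membrane-bound fraction and 19
#' chromosomes with ~3% unplaced genes.
#'
#' @param seed mandatory integer seed; every downstream draw derives from
#'   it.
#' @param nSpecies number of species.
#' @param nClusters number of planted orthogroups.
#' @param clusterCopies integer vector (recycled to `nClusters`): gene
#'   copies per species in each cluster.
#' @param clusterSubfamilies subfamily label per cluster (recycled).
#' @param domainTypeMix optional probabilities over
#'   `c(IV_a, IV_b, IV_c, IV_4)` used to draw cluster domain types; the
#'   default `NULL` derives types from subfamilies (III -> IV_c, one II
#'   cluster -> IV_4, else IV_b).
#' @param mutationRate per-site substitution probability between the
#'   cluster ancestor and each species copy.
#' @param clusterDivergence per-site rate separating cluster ancestors from
#'   their subfamily consensus.
#' @param asProb probability that a gene carries alternative-splicing
#'   forms.
#' @param asCategoryProbs probabilities of variant categories
#'   `c(utr_only, domain_loss, other)`. A UTR-only variant keeps the CDS
#'   and changes only untranslated exon structure, so its protein is
#'   identical to the canonical one (the identical-protein phenomenon).
#' @param asExtraMax maximum extra isoforms per AS gene.
#' @param tmhFraction probability a gene carries a planted transmembrane
#'   helix.
#' @param chromCount chromosomes per species.
#' @param unplacedFraction fraction of genes on unassigned scaffolds.
#' @param nSpeciesSpecific extra single-species genes outside all clusters.
#' @param anchorsPerSubfamily free anchor (reference) domains emitted per
#'   subfamily, drawn near the subfamily consensus.
#' @param anchorsPerCluster partner anchors emitted per cluster, drawn from
#'   the cluster ancestor at `anchorDivergence` — emulating an outgroup
#'   genus whose members interleave with the clusters on the tree.
#' @param anchorDivergence per-site rate separating partner anchors from
#'   their cluster ancestor.
#' @param tissues expression condition labels.
#' @param exprSpecies number of species covered by the expression matrix.
#' @param withinCorr,betweenCorr latent Gaussian-copula correlation within
#'   and between expression blocks (blocks = clusters).
#' @return validated config list (class `"gataSimConfig"`).
#' @export
simConfig <- function(seed,
                      nSpecies = 7L,
                      nClusters = 21L,
                      clusterCopies = c(4L, 2L, 2L, rep(1L, 18L)),
                      clusterSubfamilies = c(rep("III", 4), rep("I", 10),
                                             rep("II", 6), "IV"),
                      domainTypeMix = NULL,
                      mutationRate = 0.05,
                      clusterDivergence = 0.15,
                      asProb = 0.30,
                      asCategoryProbs = c(utr_only = 0.5, domain_loss = 0.25,
                                          other = 0.25),
                      asExtraMax = 3L,
                      tmhFraction = 5 / 389,
                      chromCount = 19L,
                      unplacedFraction = 0.03,
                      nSpeciesSpecific = 4L,
                      anchorsPerSubfamily = 2L,
                      anchorsPerCluster = 1L,
                      anchorDivergence = 0.25,
                      tissues = c("leaf", "phloem", "xylem", "root"),
                      exprSpecies = 2L,
                      withinCorr = 0.9,
                      betweenCorr = 0.0) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(mutationRate, clusterDivergence, asProb, tmhFraction,
             unplacedFraction, withinCorr, betweenCorr, asCategoryProbs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(asCategoryProbs) - 1) > 1e-9)
    stop("asCategoryProbs must sum to 1")
  if (!is.null(domainTypeMix) && abs(sum(domainTypeMix) - 1) > 1e-9)
    stop("domainTypeMix must sum to 1")
  cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
              nClusters = as.integer(nClusters),
              clusterCopies = rep_len(as.integer(clusterCopies), nClusters),
              clusterSubfamilies = rep_len(clusterSubfamilies, nClusters),
              domainTypeMix = domainTypeMix,
              mutationRate = mutationRate,
              clusterDivergence = clusterDivergence,
              asProb = asProb, asCategoryProbs = asCategoryProbs,
              asExtraMax = as.integer(asExtraMax),
              tmhFraction = tmhFraction,
              chromCount = as.integer(chromCount),
              unplacedFraction = unplacedFraction,
              nSpeciesSpecific = as.integer(nSpeciesSpecific),
              anchorsPerSubfamily = as.integer(anchorsPerSubfamily),
              anchorsPerCluster = as.integer(anchorsPerCluster),
              anchorDivergence = anchorDivergence,
              tissues = tissues, exprSpecies = as.integer(exprSpecies),
              withinCorr = withinCorr, betweenCorr = betweenCorr)
  class(cfg) <- "gataSimConfig"
  cfg
}

#' Seeded per-site substitution
#'
#' Each position is substituted with probability `rate` to a uniformly
#' random different residue from `alphabet`; `protected` positions are
#' never touched.
#'
#' @param seq amino-acid string.
#' @param rate per-site substitution probability.
#' @param protected integer positions exempt from substitution.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @param alphabet residues substitutions are drawn from (default the 20
#'   standard residues).
#' @return mutated string.
#' @export
mutateSequence <- function(seq, rate, protected = integer(), seed = NULL,
                           alphabet = AA20) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    hit <- setdiff(hit, protected)
    for (i in hit) {
      alt <- setdiff(alphabet, chars[i])
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Degrade a complete domain to a partial (IV_p) form
#'
#' Substitutes one of the four cysteines (default C4) by serine, producing
#' an incomplete tetrad for profile-based partial-domain truth.
#'
#' @param protein protein string.
#' @param hit one complete-hit row ([scanZincFinger()] layout).
#' @param which which cysteine to remove (1-4).
#' @return modified protein string.
#' @export
degradeToPartial <- function(protein, hit, which = 4L) {
  pos <- c(hit$c1, hit$c2, hit$c3, hit$c4)[which]
  paste0(substr(protein, 1, pos - 1L), "S",
         substr(protein, pos + 1L, nchar(protein)))
}

sampleFlank <- function(n) {
  if (n <= 0L) return("")
  paste(sample(FLANK_AA, n, replace = TRUE), collapse = "")
}

sampleBasic <- function(n = 15L) {
  paste(ifelse(stats::runif(n) < 0.5, sample(c("K", "R"), n, replace = TRUE),
               sample(FLANK_AA, n, replace = TRUE)), collapse = "")
}

## reverse-translate one protein (plus stop) to codons, standard code
CODONS_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

reverseTranslate <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  cods <- vapply(aas, function(a) {
    opts <- CODONS_OF[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  c(cods, "TAA")
}

## map a codon range [a, b] (1-based codons of the full CDS incl. stop)
## through locus-local CDS chunks to nt intervals
mapCodonRange <- function(chunks, a, b) {
  ntFrom <- 3L * (a - 1L) + 1L
  ntTo <- 3L * b
  lens <- IRanges::width(chunks)
  cum <- cumsum(lens)
  out <- IRanges::IRanges()
  for (i in seq_along(chunks)) {
    lo <- cum[i] - lens[i] + 1L
    hi <- cum[i]
    s <- max(lo, ntFrom); e <- min(hi, ntTo)
    if (s <= e) {
      off <- IRanges::start(chunks)[i] - lo
      out <- c(out, IRanges::IRanges(s + off, e + off))
    }
  }
  out
}

## build the local (sense-strand) structure of one gene locus
buildLocus <- function(protein, domSpan) {
  len <- nchar(protein)
  codons <- reverseTranslate(protein)
  nCod <- length(codons)
  nEx <- sample(2:4, 1L)
  cuts <- if (nEx > 1L) sort(sample(seq_len(nCod - 1L), nEx - 1L)) else
    integer()
  sizes <- diff(c(0L, cuts, nCod)) * 3L
  u5 <- sample(40:120, 1L); u3 <- sample(40:120, 1L); xu <- 60L
  intr <- sample(80:200, nEx, replace = TRUE)  # intron0 (extra UTR) + rest

  pos <- 1L
  extraU5 <- IRanges::IRanges(pos, pos + xu - 1L); pos <- pos + xu + intr[1]
  exons <- IRanges::IRanges(); cds <- IRanges::IRanges()
  for (i in seq_len(nEx)) {
    exStart <- pos
    if (i == 1L) pos <- pos + u5
    cdsStart <- pos
    pos <- pos + sizes[i]
    cds <- c(cds, IRanges::IRanges(cdsStart, pos - 1L))
    if (i == nEx) pos <- pos + u3
    exons <- c(exons, IRanges::IRanges(exStart, pos - 1L))
    if (i < nEx) pos <- pos + intr[i + 1L]
  }
  L <- pos - 1L

  ## sense nucleotide sequence
  nt <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cdsNt <- strsplit(paste(codons, collapse = ""), "")[[1]]
  k <- 1L
  for (i in seq_along(cds)) {
    idx <- IRanges::start(cds)[i]:IRanges::end(cds)[i]
    nt[idx] <- cdsNt[k:(k + length(idx) - 1L)]
    k <- k + length(idx)
  }
  list(protein = protein, codons = codons, nCodons = nCod, exons = exons,
       cds = cds, extraU5 = extraU5, length = L,
       seq = paste(nt, collapse = ""), domSpan = domSpan)
}

## alternative-splicing variants on a built locus
spliceVariants <- function(locus, categories) {
  out <- list()
  len <- nchar(locus$protein)
  c1 <- locus$domSpan[1]; c4 <- locus$domSpan[2]
  for (cat in categories) {
    if (cat == "utr_only") {
      out[[length(out) + 1L]] <- list(
        category = "utr_only", exons = c(locus$extraU5, locus$exons),
        cds = locus$cds, protein = locus$protein)
    } else if (cat == "domain_loss") {
      if (c1 > 30L) { a <- 1L; b <- c1 - 10L }
      else { a <- min(c4 + 5L, len - 4L); b <- len }
      out[[length(out) + 1L]] <- list(
        category = "domain_loss", exons = locus$exons,
        cds = mapCodonRange(locus$cds, a, b),
        protein = substr(locus$protein, a, b))
    } else {  # other: in-frame deletion of 10 codons away from the domain
      ## placed outside the domain and its aligned flanks, as splice
      ## variation in this family leaves the DNA-binding region intact
      if (len - c4 >= 42L) { a <- c4 + 32L; b <- a + 9L }
      else { a <- max(2L, c1 - 25L); b <- a + 9L }
      keep1 <- mapCodonRange(locus$cds, 1L, a - 1L)
      keep2 <- mapCodonRange(locus$cds, b + 1L, locus$nCodons)
      out[[length(out) + 1L]] <- list(
        category = "other", exons = locus$exons,
        cds = sortRanges(c(keep1, keep2)),
        protein = paste0(substr(locus$protein, 1, a - 1L),
                         substr(locus$protein, b + 1L, len)))
    }
  }
  out
}

#' Generate a synthetic multi-species family with ground truth
#'
#' Draws cluster ancestors from synthetic subfamily consensus domains
#' (cysteines and the two subfamily-diagnostic residues are never mutated),
#' diverges species copies at the configured rate, embeds every isoform in
#' an exon/intron/UTR gene structure on per-species chromosomes, plants
#' alternative-splicing variants, transmembrane helices and a
#' block-structured expression matrix, and records complete truth tables.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [simConfig()] object.
#' @return object of class `"gataSimulation"`: list with `genesBySpecies`,
#'   `genomes` (per-species [Biostrings::DNAStringSet]), `proteins`,
#'   `anchors` (anchor id -> subfamily), `anchorProteins`, `expression`
#'   matrix, `truth` (data.frames `genes`, `isoforms`, `expression`), and
#'   `config`.
#' @export
makeFamily <- function(config) {
  stopifnot(inherits(config, "gataSimConfig"))
  withSeed(config$seed, makeFamilyImpl(config))
}

makeFamilyImpl <- function(cfg) {
  speciesNames <- sprintf("sp%02d", seq_len(cfg$nSpecies))
  types <- c("IV_a", "IV_b", "IV_c", "IV_4")

  ## --- cluster ancestors -------------------------------------------------
  clusterType <- character(cfg$nClusters)
  iv4Given <- FALSE
  for (i in seq_len(cfg$nClusters)) {
    sf <- cfg$clusterSubfamilies[i]
    if (!is.null(cfg$domainTypeMix)) {
      clusterType[i] <- sample(types, 1L, prob = cfg$domainTypeMix)
    } else if (sf == "III") clusterType[i] <- "IV_c"
    else if (sf == "II" && !iv4Given) { clusterType[i] <- "IV_4"; iv4Given <- TRUE }
    else clusterType[i] <- "IV_b"
  }

  ancestors <- list()   # per cluster-copy: protein, protected, cpos, meta
  clusterAnc <- list()  # first-copy ancestor per cluster (partner anchors)
  for (i in seq_len(cfg$nClusters)) {
    sf <- cfg$clusterSubfamilies[i]
    base <- subfamilyDomain(sf, clusterType[i])
    clDom <- mutateSequence(base$seq, cfg$clusterDivergence,
                            protected = base$protected,
                            alphabet = setdiff(AA20, "C"))
    for (cp in seq_len(cfg$clusterCopies[i])) {
      dom <- if (cp == 1L) clDom else
        mutateSequence(clDom, 0.05, protected = base$protected,
                       alphabet = setdiff(AA20, "C"))
      nLen <- if (sf == "IV") sample(8:20, 1L) else sample(120:200, 1L)
      cLen <- if (sf == "IV") sample(150:220, 1L) else sample(30:60, 1L)
      prot <- paste0("M", sampleFlank(nLen - 1L), dom, sampleBasic(15L),
                     sampleFlank(cLen))
      ancestors[[length(ancestors) + 1L]] <- list(
        cluster = sprintf("C%02d", i), subfamily = sf,
        type = clusterType[i],
        protein = prot,
        cpos = base$cpos + nLen,
        protected = base$protected + nLen)
      if (cp == 1L)
        clusterAnc[[sprintf("C%02d", i)]] <-
          ancestors[[length(ancestors)]]
    }
  }

  ## --- genes per species --------------------------------------------------
  geneRows <- list(); isoRows <- list()
  genesBySpecies <- stats::setNames(vector("list", cfg$nSpecies), speciesNames)
  segmentsBySpecies <- stats::setNames(
    rep(list(list()), cfg$nSpecies), speciesNames)
  proteins <- character()

  makeGene <- function(sp, gid, anc, tmh) {
    prot <- mutateSequence(anc$protein, cfg$mutationRate,
                           protected = anc$protected,
                           alphabet = setdiff(AA20, "C"))
    tmhSpan <- c(NA_integer_, NA_integer_)
    if (tmh) {
      ins <- paste(sample(c("I", "L", "V", "F"), 23L, replace = TRUE,
                          prob = c(.3, .3, .25, .15)), collapse = "")
      at <- anc$cpos[4] + 20L   # after the basic region
      prot <- paste0(substr(prot, 1, at), ins,
                     substr(prot, at + 1L, nchar(prot)))
      tmhSpan <- c(at + 1L, at + 23L)
    }
    locus <- buildLocus(prot, anc$cpos[c(1, 4)])
    cats <- character()
    if (stats::runif(1) < cfg$asProb) {
      nx <- sample(seq_len(cfg$asExtraMax), 1L,
                   prob = c(0.6, 0.3, 0.1)[seq_len(cfg$asExtraMax)])
      cats <- sample(names(cfg$asCategoryProbs), nx, replace = TRUE,
                     prob = cfg$asCategoryProbs)
    }
    vars <- spliceVariants(locus, cats)
    list(gid = gid, anc = anc, locus = locus, vars = vars, tmhSpan = tmhSpan)
  }

  built <- stats::setNames(rep(list(list()), cfg$nSpecies), speciesNames)
  for (sp in speciesNames) {
    gi <- 0L
    for (a in ancestors) {
      gi <- gi + 1L
      gid <- sprintf("%sG%02d", sp, gi)
      built[[sp]][[gid]] <- c(makeGene(sp, gid, a,
                                       stats::runif(1) < cfg$tmhFraction),
                              list(cluster = a$cluster,
                                   subfamily = a$subfamily, type = a$type))
    }
  }
  ## species-specific extras: unique domains, a single random species each
  if (cfg$nSpeciesSpecific > 0L) {
    for (k in seq_len(cfg$nSpeciesSpecific)) {
      sf <- sample(c("I", "II"), 1L)
      base <- subfamilyDomain(sf, "IV_b")
      dom <- mutateSequence(base$seq, 0.3, protected = base$protected,
                            alphabet = setdiff(AA20, "C"))
      nLen <- sample(120:200, 1L)
      prot <- paste0("M", sampleFlank(nLen - 1L), dom, sampleBasic(15L),
                     sampleFlank(sample(30:60, 1L)))
      anc <- list(cluster = "specific", subfamily = sf, type = "IV_b",
                  protein = prot, cpos = base$cpos + nLen,
                  protected = base$protected + nLen)
      sp <- sample(speciesNames, 1L)
      gid <- sprintf("%sGS%02d", sp, k)
      built[[sp]][[gid]] <- c(makeGene(sp, gid, anc, FALSE),
                              list(cluster = "specific", subfamily = sf,
                                   type = "IV_b"))
    }
  }

  ## --- chromosome layout and GeneModel construction -----------------------
  for (sp in speciesNames) {
    chromCursor <- stats::setNames(rep(1L, cfg$chromCount),
                                   sprintf("Chr%02d", seq_len(cfg$chromCount)))
    scafN <- 0L
    genes <- list()
    for (gid in names(built[[sp]])) {
      b <- built[[sp]][[gid]]
      placed <- stats::runif(1) >= cfg$unplacedFraction
      strand <- sample(c("+", "-"), 1L)
      L <- b$locus$length
      if (placed) {
        chrom <- sample(names(chromCursor), 1L)
        gap <- sample(200:400, 1L)
        offset <- chromCursor[[chrom]] + gap
        chromCursor[[chrom]] <- offset + L
        seg <- b$locus$seq
        if (strand == "-")
          seg <- as.character(reverseComplement(DNAString(seg)))
        segmentsBySpecies[[sp]][[length(segmentsBySpecies[[sp]]) + 1L]] <-
          list(chrom = chrom, start = offset, seq = seg)
      } else {
        scafN <- scafN + 1L
        chrom <- sprintf("scaffold_%03d", scafN)
        offset <- 101L
        seg <- b$locus$seq
        if (strand == "-")
          seg <- as.character(reverseComplement(DNAString(seg)))
        segmentsBySpecies[[sp]][[length(segmentsBySpecies[[sp]]) + 1L]] <-
          list(chrom = chrom, start = offset, seq = seg)
      }
      toGenomic <- function(r) {
        if (strand == "+")
          IRanges::IRanges(offset + IRanges::start(r) - 1L,
                           offset + IRanges::end(r) - 1L)
        else
          sortRanges(IRanges::IRanges(offset + L - IRanges::end(r),
                                offset + L - IRanges::start(r)))
      }
      mkTx <- function(tid, exons, cds, protein) {
        gex <- toGenomic(exons); gcd <- toGenomic(cds)
        cdsSpan <- range(gcd)
        left <- IRanges::restrict(gex, end = IRanges::start(cdsSpan) - 1L)
        right <- IRanges::restrict(gex, start = IRanges::end(cdsSpan) + 1L)
        if (strand == "+") { u5 <- left; u3 <- right }
        else { u5 <- right; u3 <- left }
        methods::new("TranscriptModel", transcriptId = tid, exons = gex,
                     cds = gcd, utr5 = u5, utr3 = u3, protein = protein,
                     status = "ok")
      }
      txs <- list(mkTx(paste0(gid, "a"), b$locus$exons, b$locus$cds,
                       b$locus$protein))
      isoRows[[length(isoRows) + 1L]] <- data.frame(
        transcript_id = paste0(gid, "a"), gene_id = gid, species = sp,
        category = "canonical", utr_only = FALSE, stringsAsFactors = FALSE)
      for (vi in seq_along(b$vars)) {
        v <- b$vars[[vi]]
        tid <- paste0(gid, letters[vi + 1L])
        txs[[length(txs) + 1L]] <- mkTx(tid, v$exons, v$cds, v$protein)
        isoRows[[length(isoRows) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, species = sp,
          category = v$category, utr_only = v$category == "utr_only",
          stringsAsFactors = FALSE)
      }
      for (t in txs) proteins[t@transcriptId] <- t@protein
      genes[[gid]] <- methods::new("GeneModel", geneId = gid, species = sp,
                                   chromosome = chrom, strand = strand,
                                   placed = placed, transcripts = txs)
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        gene_id = gid, species = sp, cluster = b$cluster,
        subfamily = b$subfamily, type = b$type, chromosome = chrom,
        placed = placed, strand = strand,
        dom_c1 = b$anc$cpos[1], dom_c4 = b$anc$cpos[4],
        tmh_start = b$tmhSpan[1], tmh_end = b$tmhSpan[2],
        n_isoforms = length(txs), stringsAsFactors = FALSE)
    }
    genesBySpecies[[sp]] <- genes
  }

  ## assemble chromosome sequences from placed segments
  genomes <- stats::setNames(vector("list", cfg$nSpecies), speciesNames)
  for (sp in speciesNames) {
    segs <- segmentsBySpecies[[sp]]
    chroms <- list()
    for (s in segs) {
      cur <- if (is.null(chroms[[s$chrom]])) "" else chroms[[s$chrom]]
      padLen <- s$start - 1L - nchar(cur)
      chroms[[s$chrom]] <- paste0(cur, randomDna(padLen), s$seq)
    }
    chroms <- lapply(chroms, function(x) paste0(x, randomDna(100L)))
    genomes[[sp]] <- DNAStringSet(unlist(chroms))
  }

  ## --- anchors -------------------------------------------------------------
  ## partner anchors: outgroup-genus orthologs interleaving with the
  ## clusters on the domain tree (one or more per cluster), plus a few free
  ## anchors near each subfamily consensus
  anchors <- character(); anchorProteins <- character()
  for (clId in names(clusterAnc)) {
    ca <- clusterAnc[[clId]]
    for (k in seq_len(cfg$anchorsPerCluster)) {
      id <- sprintf("ANC_%s_%s_%d", ca$subfamily, clId, k)
      anchorProteins[id] <- mutateSequence(ca$protein, cfg$anchorDivergence,
                                           protected = ca$protected,
                                           alphabet = setdiff(AA20, "C"))
      anchors[id] <- ca$subfamily
    }
  }
  for (sf in c("I", "II", "III", "IV")) {
    base <- subfamilyDomain(sf, if (sf == "III") "IV_c" else "IV_b")
    for (k in seq_len(cfg$anchorsPerSubfamily)) {
      dom <- mutateSequence(base$seq, 0.10, protected = base$protected,
                            alphabet = setdiff(AA20, "C"))
      nLen <- if (sf == "IV") sample(8:20, 1L) else sample(120:200, 1L)
      id <- sprintf("ANC_%s_%d", sf, k)
      anchorProteins[id] <- paste0("M", sampleFlank(nLen - 1L), dom,
                                   sampleBasic(15L),
                                   sampleFlank(sample(30:60, 1L)))
      anchors[id] <- sf
    }
  }

  ## --- expression (Gaussian copula, exponential marginals, tissue blocks) --
  truthGenes <- do.call(rbind, geneRows)
  exprSp <- speciesNames[seq_len(min(cfg$exprSpecies, cfg$nSpecies))]
  exprGenes <- truthGenes$gene_id[truthGenes$species %in% exprSp]
  blocks <- truthGenes$cluster[truthGenes$species %in% exprSp]
  blocks[blocks == "specific"] <-
    paste0("solo", seq_len(sum(blocks == "specific")))
  nt <- length(cfg$tissues)
  blockLatent <- list(); blockScale <- list()
  expr <- matrix(0, length(exprGenes), nt,
                 dimnames = list(exprGenes, cfg$tissues))
  rho <- cfg$withinCorr
  for (i in seq_along(exprGenes)) {
    bl <- blocks[i]
    if (is.null(blockLatent[[bl]])) {
      blockLatent[[bl]] <- stats::rnorm(nt)
      ## tissue-specific signature: one strongly expressed tissue per
      ## block (two orders of magnitude over baseline, as tissue-specific
      ## TF expression shows), the rest at log-uniform baseline scales
      sc <- exp(stats::runif(nt, log(1), log(30)))
      sc[sample.int(nt, 1L)] <- stats::runif(1, 200, 400)
      blockScale[[bl]] <- sc
    }
    z <- sqrt(rho) * blockLatent[[bl]] +
      sqrt(1 - rho) * stats::rnorm(nt)
    expr[i, ] <- stats::qexp(stats::pnorm(z), rate = 1 / blockScale[[bl]])
  }

  out <- list(genesBySpecies = genesBySpecies, genomes = genomes,
              proteins = proteins, anchors = anchors,
              anchorProteins = anchorProteins, expression = expr,
              truth = list(genes = truthGenes,
                           isoforms = do.call(rbind, isoRows),
                           expression = data.frame(gene_id = exprGenes,
                                                   block = blocks,
                                                   stringsAsFactors = FALSE)),
              config = cfg)
  class(out) <- "gataSimulation"
  out
}

randomDna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a simulation to disk in standard formats
#'
#' Per species: `genome_<sp>.fa`, `annotation_<sp>.gff3`,
#' `proteins_<sp>.fa`; plus `anchors.fa`, `expression.csv` and the truth
#' tables as TSV.
#'
#' @param sim a `"gataSimulation"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genesBySpecies)) {
    writeXStringSet(sim$genomes[[sp]],
                    file.path(dir, paste0("genome_", sp, ".fa")))
    writeGeneModelsGFF3(sim$genesBySpecies[[sp]],
                        file.path(dir, paste0("annotation_", sp, ".gff3")))
    ids <- names(familyProteins(sim$genesBySpecies[[sp]]))
    writeXStringSet(AAStringSet(sim$proteins[ids]),
                    file.path(dir, paste0("proteins_", sp, ".fa")))
  }
  writeXStringSet(AAStringSet(sim$anchorProteins), file.path(dir, "anchors.fa"))
  utils::write.csv(data.frame(gene_id = rownames(sim$expression),
                              sim$expression, check.names = FALSE),
                   file.path(dir, "expression.csv"), row.names = FALSE,
                   quote = FALSE)
  for (nm in names(sim$truth))
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
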