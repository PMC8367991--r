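## ---------------------------------------------------------------------------
## domain_align_phylo: cysteine-anchored alignment, p-distances, in-package
## neighbor-joining with deterministic tie-breaks, bootstrap bipartition
## support, anchor-based subfamily assignment, and multi-species gene-cluster
## (PC) extraction.
## ---------------------------------------------------------------------------

#' Align complete domains on their cysteine anchors
#'
#' Complete class-IV domains share the C1--C4 tetrad; rows are aligned by
#' fixing the four cysteines to common columns. Within each spacer the
#' residues are left-justified and gaps are inserted immediately before the
#' next cysteine; flanking residues (`flank5` before C1, `flank3` after C4,
#' covering the basic region) are taken from the source proteins and padded
#' with end-gaps where a protein is shorter. Partial (IV_p) hits cannot be
#' anchored and are rejected.
#'
#' @param hits data.frame of complete hits (layout of [scanZincFinger()]);
#'   one row per alignment member.
#' @param proteins named character vector of source proteins, indexed by
#'   `hits$protein_id`.
#' @param memberIds optional row names for the alignment; defaults to
#'   `protein_id`, suffixed `.d2`, `.d3`, ... for extra domains of the same
#'   protein.
#' @param flank5,flank3 flank widths in residues (defaults 7 and 25).
#' @return [DomainAlignment-class].
#' @export
anchorAlign <- function(hits, proteins, memberIds = NULL,
                        flank5 = 7L, flank3 = 25L) {
  if (!nrow(hits)) stop("no domains to align")
  if (any(hits$type == "IV_p"))
    stop("partial (IV_p) domains cannot be anchor-aligned: ",
         paste(hits$protein_id[hits$type == "IV_p"], collapse = ","))
  if (is.null(memberIds)) {
    memberIds <- hits$protein_id
    dup <- stats::ave(seq_along(memberIds), memberIds, FUN = seq_along)
    memberIds[dup > 1] <- paste0(memberIds[dup > 1], ".d", dup[dup > 1])
  }
  maxS1 <- max(hits$s1); maxS2 <- max(hits$s2); s3 <- SPACER_BOUNDS$s3[1]

  pad <- function(x, n, left = FALSE) {
    g <- strrep("-", n - nchar(x))
    if (left) paste0(g, x) else paste0(x, g)
  }
  rows <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    p <- proteins[[hits$protein_id[i]]]
    if (is.null(p) || is.na(p))
      stop("no protein sequence for ", hits$protein_id[i])
    c1 <- hits$c1[i]; c2 <- hits$c2[i]; c3 <- hits$c3[i]; c4 <- hits$c4[i]
    lf <- substr(p, max(1L, c1 - flank5), c1 - 1L)
    rf <- substr(p, c4 + 1L, min(nchar(p), c4 + flank3))
    rows[i] <- paste0(
      pad(lf, flank5, left = TRUE), "C",
      pad(substr(p, c1 + 1L, c2 - 1L), maxS1), "C",
      pad(substr(p, c2 + 1L, c3 - 1L), maxS2), "C",
      substr(p, c3 + 1L, c4 - 1L), "C",
      pad(rf, flank3))
  }
  names(rows) <- memberIds
  a1 <- flank5 + 1L
  a2 <- a1 + maxS1 + 1L
  a3 <- a2 + maxS2 + 1L
  a4 <- a3 + s3 + 1L
  methods::new("DomainAlignment", rows = rows,
               anchorColumns = as.integer(c(a1, a2, a3, a4)))
}

#' Pairwise p-distance matrix of an alignment
#'
#' p-distance = mismatches / compared columns, with pairwise deletion of
#' columns where either row has a gap. A pair with no comparable column is
#' an error.
#'
#' @param aln [DomainAlignment-class] (or character matrix) with >= 3 rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(aln) {
  m <- if (is.matrix(aln)) aln else alignmentMatrix(aln)
  if (nrow(m) < 3L) stop("need at least 3 rows")
  n <- nrow(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("rows ", rownames(m)[i], " and ", rownames(m)[j],
             " share no comparable columns")
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Classic Saitou--Nei agglomeration. Ties in the Q matrix are broken by the
#' smallest (row, column) index pair in the current matrix order (original
#' taxon order, merged nodes appended). Negative branch lengths are clamped
#' to zero with the deficit transferred to the sister edge, preserving the
#' pair's total length.
#'
#' @param d symmetric non-negative distance matrix with row/col names,
#'   >= 3 taxa.
#' @return unrooted `phylo` tree (trifurcating root node).
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || is.null(rownames(d)))
    stop("d must be a square labelled matrix")
  if (any(is.na(d)) || any(d < 0)) stop("d must be finite and non-negative")
  if (max(abs(d - t(d))) > 1e-12) stop("d must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")

  clampPair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }

  nodes <- rownames(d)                 # newick fragment per active node
  D <- d
  while (length(nodes) > 3L) {
    N <- length(nodes)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    ## smallest (i, j) with i < j among ties
    idx <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (N - 2))
    bj <- D[i, j] - bi
    b <- clampPair(bi, bj)
    newFrag <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], b[1], nodes[j], b[2])
    dn <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    nodes <- c(nodes[keep], newFrag)
    rownames(D) <- colnames(D) <- NULL
  }
  ## final three-point join
  bx <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  by <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  bz <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[1], max(bx, 0), nodes[2], max(by, 0),
                 nodes[3], max(bz, 0))
  ape::read.tree(text = nwk)
}

## canonical bipartition key of a tip-label subset
splitKey <- function(side, allTips) {
  other <- setdiff(allTips, side)
  s1 <- paste(sort(side), collapse = ",")
  s2 <- paste(sort(other), collapse = ",")
  if (s1 <= s2) paste(s1, s2, sep = "||") else paste(s2, s1, sep = "||")
}

## bipartition keys for every internal node of a tree (node order
## Ntip+1 ... Ntip+Nnode); trivial splits get NA
treeSplitKeys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(seq_along(pp), function(k) {
    side <- labs[pp[[k]]]
    if (length(side) <= 1L || length(side) >= length(labs) - 1L)
      return(NA_character_)
    splitKey(side, labs)
  }, character(1))
}

#' Bootstrap support for the neighbor-joining tree of an alignment
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times (seeded and
#' reproducible), rebuilds an NJ tree per replicate, and reports for each
#' internal edge of the reference tree the percentage of replicate trees
#' containing the same bipartition. Supports are written to
#' `tree$node.label` (empty for trivial splits).
#'
#' @param aln [DomainAlignment-class] or character matrix.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed for the column resampling.
#' @return the reference `phylo` tree with `node.label` support percentages;
#'   alignments with fewer than 4 rows return the tree with empty supports.
#' @export
bootstrapSupport <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  m <- if (is.matrix(aln)) aln else alignmentMatrix(aln)
  ref <- njTree(pDistanceMatrix(m))
  if (nrow(m) < 4L) {
    ref$node.label <- rep("", ref$Nnode)
    return(ref)
  }
  counts <- new.env(parent = emptyenv())
  withSeed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      bt <- njTree(pDistanceMatrix(m[, cols, drop = FALSE]))
      for (k in unique(stats::na.omit(treeSplitKeys(bt))))
        assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L,
               counts)
    }
  })
  refKeys <- treeSplitKeys(ref)
  ref$node.label <- vapply(refKeys, function(k) {
    if (is.na(k)) return("")
    cnt <- if (exists(k, counts)) get(k, counts) else 0L
    format(roundHalfUp(100 * cnt / replicates, 1))
  }, character(1))
  ref
}

#' Assign subfamilies from anchor leaves
#'
#' Each non-anchor leaf receives the subfamily of its nearest anchor leaf by
#' patristic (tree path) distance; leaves exactly equidistant (within
#' relative tolerance 1e-9) to anchors of different subfamilies are labelled
#' `"unresolved"`.
#'
#' @param tree `phylo` with anchors among the tips.
#' @param anchors named character vector: anchor tip label -> subfamily.
#' @return named character vector: non-anchor tip -> subfamily label.
#' @export
assignSubfamily <- function(tree, anchors) {
  if (!length(anchors)) stop("no anchors supplied")
  if (!all(names(anchors) %in% tree$tip.label))
    stop("anchor tips missing from tree: ",
         paste(setdiff(names(anchors), tree$tip.label), collapse = ","))
  d <- ape::cophenetic.phylo(tree)
  members <- setdiff(tree$tip.label, names(anchors))
  out <- setNames(character(length(members)), members)
  for (m in members) {
    dm <- d[m, names(anchors)]
    best <- min(dm)
    near <- unique(anchors[dm <= best + 1e-9 * max(1, best)])
    out[m] <- if (length(near) == 1L) near else "unresolved"
  }
  out
}

#' Extract multi-species gene clusters (PCs) from a supported tree
#'
#' A cluster is a maximal clade (no qualifying clade contains it) of the
#' midpoint-rooted tree whose leaves are all in-genus (no anchors), span at
#' least `minSpecies` distinct species, and whose defining bipartition has
#' bootstrap support of at least `minSupport` (edges without support values
#' qualify). Remaining in-genus leaves are reported as unclustered
#' (species-specific genes). Clusters are numbered `PC01`, `PC02`, ... by
#' tree traversal order within subfamily, subfamily III first.
#'
#' @param tree supported `phylo` (e.g. from [bootstrapSupport()]).
#' @param speciesOf named character vector: in-genus tip -> species.
#' @param minSpecies minimum distinct species per cluster (default 5).
#' @param minSupport minimum bootstrap percentage (default 50).
#' @param anchors optional named anchor -> subfamily vector (anchor tips are
#'   excluded from clusters); also used to label cluster subfamilies.
#' @param outgroup optional tip label to root on instead of midpoint
#'   rooting.
#' @return list of [GeneCluster-class]; attribute `"unclustered"` holds the
#'   unassigned in-genus tips.
#' @export
detectClusters <- function(tree, speciesOf, minSpecies = 5L,
                           minSupport = 50, anchors = character(),
                           outgroup = NULL) {
  ingenus <- setdiff(tree$tip.label, names(anchors))
  unknown <- setdiff(ingenus, names(speciesOf))
  if (length(unknown))
    stop("leaves without species label: ", paste(unknown, collapse = ","))

  ## supports live on bipartitions; collect them before re-rooting
  supKeys <- treeSplitKeys(tree)
  supVals <- if (is.null(tree$node.label)) rep(NA_real_, tree$Nnode) else
    suppressWarnings(as.numeric(tree$node.label))
  supOf <- setNames(supVals, supKeys)
  supOf <- supOf[!is.na(names(supOf))]

  rooted <- if (!is.null(outgroup))
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  else phangorn::midpoint(tree)

  ntip <- length(rooted$tip.label)
  pp <- ape::prop.part(rooted)
  labs <- attr(pp, "labels")
  allTips <- tree$tip.label
  nodeInfo <- lapply(seq_along(pp), function(k) {
    tips <- labs[pp[[k]]]
    key <- if (length(tips) <= 1L || length(tips) >= length(labs) - 1L)
      NA_character_ else splitKey(tips, allTips)
    sup <- if (!is.na(key) && key %in% names(supOf)) supOf[[key]] else NA_real_
    list(node = ntip + k, tips = tips, support = sup)
  })

  qualifies <- vapply(nodeInfo, function(ni) {
    if (any(ni$tips %in% names(anchors))) return(FALSE)
    if (length(unique(speciesOf[ni$tips])) < minSpecies) return(FALSE)
    is.na(ni$support) || ni$support >= minSupport
  }, logical(1))

  ## maximality: drop qualifying clades nested in a larger qualifying clade
  qIdx <- which(qualifies)
  keep <- vapply(qIdx, function(k) {
    !any(vapply(qIdx, function(k2) {
      k2 != k && all(nodeInfo[[k]]$tips %in% nodeInfo[[k2]]$tips)
    }, logical(1)))
  }, logical(1))
  qIdx <- qIdx[keep]

  ## traversal order: preorder position of each clade's root node
  preord <- preorderNodes(rooted)
  ord <- order(match(vapply(qIdx, function(k) nodeInfo[[k]]$node,
                            numeric(1)), preord))
  qIdx <- qIdx[ord]

  subfamOf <- function(tips) {
    if (!length(anchors)) return("unassigned")
    sf <- assignSubfamily(tree, anchors)[tips]
    names(sort(table(sf), decreasing = TRUE))[1]
  }
  subs <- vapply(qIdx, function(k) subfamOf(nodeInfo[[k]]$tips), character(1))
  sfOrder <- order(subs != "III", match(subs, unique(subs)))
  qIdx <- qIdx[sfOrder]; subs <- subs[sfOrder]

  clusters <- vector("list", length(qIdx))
  for (i in seq_along(qIdx)) {
    tips <- nodeInfo[[qIdx[i]]]$tips
    sc <- table(speciesOf[tips])
    clusters[[i]] <- methods::new("GeneCluster",
      pcId = sprintf("PC%02d", i), members = tips,
      speciesCounts = setNames(as.integer(sc), names(sc)),
      support = nodeInfo[[qIdx[i]]]$support, subfamily = subs[i])
  }
  clustered <- unlist(lapply(clusters, clusterMembers))
  attr(clusters, "unclustered") <- setdiff(ingenus, clustered)
  clusters
}

## preorder (root-first) node visiting order
preorderNodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  unique(c(length(tr$tip.label) + 1L, tr$edge[, 2]))
}

#' TF-per-gene ratio per species and cluster
#'
#' For every cluster and species: the number of coding isoforms (TFs)
#' carried by the member genes, divided by the member gene count; `NA`
#' where a species is absent from the cluster.
#'
#' @param clusters list of [GeneCluster-class].
#' @param geneOf named character vector: member (TF) id -> gene id.
#' @param speciesOfGene named character vector: gene id -> species.
#' @param isoformsOfGene named integer vector: gene id -> coding isoform
#'   count.
#' @return data.frame (rows = clusters, columns = species) of half-up
#'   2-decimal ratios.
#' @export
tfPerGeneRatio <- function(clusters, geneOf, speciesOfGene, isoformsOfGene) {
  species <- sort(unique(speciesOfGene))
  out <- matrix(NA_real_, length(clusters), length(species),
                dimnames = list(vapply(clusters, pcId, character(1)),
                                species))
  for (i in seq_along(clusters)) {
    gs <- unique(geneOf[clusterMembers(clusters[[i]])])
    gs <- gs[!is.na(gs)]
    for (sp in species) {
      gsp <- gs[speciesOfGene[gs] == sp]
      if (length(gsp))
        out[i, sp] <- roundHalfUp(sum(isoformsOfGene[gsp]) / length(gsp))
    }
  }
  as.data.frame(out)
}
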