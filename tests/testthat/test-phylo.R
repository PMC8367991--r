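test_that("anchor alignment pins cysteines to common columns", {
  prots <- c(b1 = domainProtein(2, 18), b2 = domainProtein(2, 18),
             c1 = domainProtein(2, 20), f1 = domainProtein(4, 18))
  twoB <- do.call(rbind, hitsFor(prots[c("b1", "b2")]))
  aln <- anchorAlign(twoB, prots)
  expect_false(any(grepl("-", substr(alignedRows(aln), 8,
                                     nchar(alignedRows(aln)[1]) - 25))))

  mixed <- do.call(rbind, hitsFor(prots[c("b1", "c1")]))
  aln2 <- anchorAlign(mixed, prots)
  m <- alignmentMatrix(aln2)
  anch <- anchorColumns(aln2)
  expect_true(all(m[, anch] == "C"))
  ## the IV_b row carries exactly 2 gaps immediately before C3
  expect_identical(unname(m["b1", (anch[3] - 2):(anch[3] - 1)]), c("-", "-"))
  expect_false(any(m["c1", ] == "-"))

  mixed4 <- do.call(rbind, hitsFor(prots[c("f1", "b2")]))
  aln3 <- anchorAlign(mixed4, prots)
  m3 <- alignmentMatrix(aln3)
  anch3 <- anchorColumns(aln3)
  ## the IV_b row gains 2 gaps before C2 (s1 4 vs 2)
  expect_identical(unname(m3["b2", (anch3[2] - 2):(anch3[2] - 1)]),
                   c("-", "-"))

  fake <- data.frame(protein_id = "x", c1 = NA, c2 = NA, c3 = NA, c4 = NA,
                     s1 = NA, s2 = NA, s3 = NA, type = "IV_p", start = 1,
                     end = 10, score = 1, terminal = "N",
                     basic_fraction = NA)
  expect_error(anchorAlign(fake, c(x = "MA")), "IV_p")
})

test_that("p-distances use pairwise deletion and match a column walk", {
  m <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
             b = strsplit("AAAAAAAAAA", "")[[1]])
  m <- rbind(m, c = strsplit("AAAAATTTTT", "")[[1]])
  d <- pDistanceMatrix(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.5)

  set.seed(4)
  for (rep in 1:20) {
    mm <- matrix(sample(c("A", "C", "G", "-"), 4 * 30, replace = TRUE,
                        prob = c(.35, .3, .25, .1)), 4, 30,
                 dimnames = list(letters[1:4], NULL))
    ok <- TRUE
    for (i in 1:3) for (j in (i + 1):4)
      if (!any(mm[i, ] != "-" & mm[j, ] != "-")) ok <- FALSE
    if (!ok) next
    d2 <- pDistanceMatrix(mm)
    for (i in 1:3) for (j in (i + 1):4) {
      comp <- mm[i, ] != "-" & mm[j, ] != "-"
      expect_equal(d2[i, j], sum(mm[i, comp] != mm[j, comp]) / sum(comp))
    }
  }

  gapPair <- rbind(a = c("A", "-"), b = c("-", "A"), c = c("A", "A"))
  expect_error(pDistanceMatrix(gapPair), "no comparable columns")
})

test_that("neighbor joining reproduces additive trees exactly", {
  ## 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njTree(d3)
  expect_equal(sort(ape::cophenetic.phylo(t3)[c("a","b","c"), c("a","b","c")],
                    method = "radix"),
               sort(d3, method = "radix"))

  set.seed(9)
  for (n in c(4, 8, 12)) {
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    mine <- njTree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), mine)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(mine)[rownames(d), colnames(d)]
                      - d)), 1e-9)
    ## independent cross-check against ape's NJ on the same matrix
    expect_equal(as.numeric(ape::dist.topo(ape::nj(as.dist(d)), mine)), 0)
  }

  dBad <- matrix(c(0, -1, -1, 0), 2)
  expect_error(njTree(matrix(0, 2, 2, dimnames = list(c("a","b"),
                                                      c("a","b")))),
               "at least 3")
  dn <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(dn), "finite")
})

test_that("negative NJ branch lengths are clamped, totals preserved", {
  ## a matrix known to produce a negative branch estimate
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 2,
                9, 10, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and label-equivariant", {
  prots <- character()
  for (i in 1:3) prots[paste0("x", i)] <- domainProtein(2, 18, nflank = 12)
  for (i in 1:3) prots[paste0("y", i)] <-
    domainProtein(2, 20, nflank = 12,
                  s2res = "WWWWWWWWWWWWWWWWWWWW")
  hits <- do.call(rbind, hitsFor(prots))
  aln <- anchorAlign(hits, prots)
  t1 <- bootstrapSupport(aln, replicates = 50, seed = 1)
  t2 <- bootstrapSupport(aln, replicates = 50, seed = 1)
  expect_identical(t1$node.label, t2$node.label)
  ## the x|y split cannot be broken by any column resample
  key <- gatafam:::treeSplitKeys(t1)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  xy <- grepl("x1,x2,x3", key) & grepl("y1,y2,y3", key)
  expect_true(any(xy))
  expect_equal(sup[xy], rep(100, sum(xy)))

  ## relabelled leaves give the same support multiset
  prots2 <- prots
  names(prots2) <- rev(names(prots))
  hits2 <- do.call(rbind, hitsFor(prots2))
  aln2 <- anchorAlign(hits2, prots2)
  t3 <- bootstrapSupport(aln2, replicates = 50, seed = 1)
  expect_setequal(unname(t3$node.label), unname(t1$node.label))
})

test_that("bootstrap counting agrees with ape's bipartition counter", {
  set.seed(6)
  prots <- character()
  for (i in 1:6) {
    base <- domainProtein(2, 18, nflank = 10)
    prots[paste0("t", i)] <- mutateSequence(base, 0.2,
                                            protected = c(11, 14, 33, 36))
  }
  hits <- do.call(rbind, hitsFor(prots))
  aln <- anchorAlign(hits, prots)
  reps <- 40L
  tree <- bootstrapSupport(aln, replicates = reps, seed = 3)
  ## rebuild the same replicate trees and count with ape::prop.clades
  m <- alignmentMatrix(aln)
  ref <- njTree(pDistanceMatrix(m))
  bts <- gatafam:::withSeed(3, {
    lapply(seq_len(reps), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      njTree(pDistanceMatrix(m[, cols, drop = FALSE]))
    })
  })
  cnt <- ape::prop.clades(ref, bts, rooted = FALSE)
  mineKeys <- gatafam:::treeSplitKeys(tree)
  mine <- suppressWarnings(as.numeric(tree$node.label))
  for (k in seq_along(mineKeys)) {
    if (is.na(mineKeys[k])) next
    expect_equal(mine[k], 100 * cnt[k] / reps, tolerance = 1e-9)
  }
})

test_that("subfamily assignment follows the nearest anchor with tie rule", {
  tr <- ape::read.tree(text =
    "((m1:1,anchorI:1):2,(m2:1,anchorII:1):2,(m3:4,anchorIII:0.5):1);")
  anch <- c(anchorI = "I", anchorII = "II", anchorIII = "III")
  sf <- assignSubfamily(tr, anch)
  expect_identical(unname(sf["m1"]), "I")
  expect_identical(unname(sf["m2"]), "II")
  expect_identical(unname(sf["m3"]), "III")

  ## exact equidistance -> unresolved
  trTie <- ape::read.tree(text = "((m1:1,anchorI:1):1,anchorII:0);")
  sfTie <- assignSubfamily(trTie, anch[1:2])
  expect_identical(unname(sfTie["m1"]), "unresolved")
  expect_error(assignSubfamily(tr, character()), "no anchors")
})

test_that("subfamily recovery stays high on drifted synthetic families", {
  hit <- 0; tot <- 0
  for (seed in 1:10) {
    sim <- tinySim(seed, mutationRate = 0.05, asProb = 0)
    prots <- c(sim$proteins, sim$anchorProteins)
    hits <- do.call(rbind, hitsFor(prots))
    aln <- anchorAlign(hits, prots, memberIds = hits$protein_id)
    tree <- njTree(pDistanceMatrix(aln))
    sf <- assignSubfamily(tree, sim$anchors)
    tg <- sim$truth$genes
    got <- sf[paste0(tg$gene_id, "a")]
    hit <- hit + sum(got == tg$subfamily)
    tot <- tot + nrow(tg)
  }
  expect_gte(hit / tot, 0.95)
})

test_that("cluster extraction: thresholds, maximality and leaf partition", {
  ## hand-built supported tree: two clean 7-species clades, one 4-species
  mk <- function(tag, n) paste0("sp", seq_len(n), "_", tag)
  ## anchors interleave between the clades so each clean clade is maximal
  nwk <- paste0("(((", paste0(mk("a", 7), ":0.1", collapse = ","),
                "):0.3,anc1:0.5):0.2,((",
                paste0(mk("b", 7), ":0.1", collapse = ","),
                "):0.3,anc2:0.5):0.2,((",
                paste0(mk("c", 4), ":0.1", collapse = ","),
                "):0.3,out:1):0.1);")
  tr <- ape::read.tree(text = nwk)
  tr$node.label <- rep("99", tr$Nnode)
  anchors <- c(anc1 = "I", anc2 = "I", out = "I")
  leaves <- setdiff(tr$tip.label, names(anchors))
  spOf <- setNames(sub("_.*", "", leaves), leaves)
  cl <- detectClusters(tr, spOf, minSpecies = 5, minSupport = 50,
                       anchors = anchors)
  expect_length(cl, 2L)
  expect_setequal(unlist(lapply(cl, function(x)
    length(clusterMembers(x)))), 7L)
  expect_setequal(attr(cl, "unclustered"), mk("c", 4))
  ## partition invariant
  expect_identical(sort(c(unlist(lapply(cl, clusterMembers)),
                          attr(cl, "unclustered"))), sort(leaves))

  ## low support disqualifies
  tr2 <- tr
  tr2$node.label <- rep("10", tr2$Nnode)
  cl2 <- detectClusters(tr2, spOf, minSpecies = 5, minSupport = 50,
                        anchors = anchors)
  expect_length(cl2, 0L)

  expect_error(detectClusters(tr, spOf[-1], anchors = anchors),
               "without species label")
})

test_that("planted orthogroups are recovered exactly without noise", {
  sim <- makeFamily(simConfig(seed = 21, nClusters = 3, clusterCopies = 1,
                              mutationRate = 0, asProb = 0,
                              nSpeciesSpecific = 0))
  prots <- c(sim$proteins, sim$anchorProteins)
  hits <- do.call(rbind, hitsFor(prots))
  aln <- anchorAlign(hits, prots, memberIds = hits$protein_id)
  tree <- njTree(pDistanceMatrix(aln))
  spOf <- setNames(sub("G.*", "", names(sim$proteins)), names(sim$proteins))
  cl <- detectClusters(tree, spOf, minSpecies = 5, minSupport = 50,
                       anchors = sim$anchors)
  expect_length(cl, 3L)
  for (x in cl) expect_true(all(speciesCounts(x) == 1L))
  expect_length(attr(cl, "unclustered"), 0L)
})

test_that("TF-per-gene ratios follow the census arithmetic", {
  cl <- methods::new("GeneCluster", pcId = "PC01",
                     members = c("gA1a", "gA1b", "gA2a", "gA2b", "gA2c",
                                 "gA2d", "gA2e", "gB1a"),
                     speciesCounts = c(spA = 7L, spB = 1L), support = 99,
                     subfamily = "III")
  geneOf <- c(gA1a = "gA1", gA1b = "gA1", gA2a = "gA2", gA2b = "gA2",
              gA2c = "gA2", gA2d = "gA2", gA2e = "gA2", gB1a = "gB1")
  spOfGene <- c(gA1 = "spA", gA2 = "spA", gB1 = "spB", gC1 = "spC")
  isoOf <- c(gA1 = 2L, gA2 = 5L, gB1 = 1L, gC1 = 1L)
  rat <- tfPerGeneRatio(list(cl), geneOf, spOfGene, isoOf)
  expect_equal(rat["PC01", "spA"], 3.50)  # 7 isoforms over 2 genes
  expect_equal(rat["PC01", "spB"], 1.00)
  expect_true(is.na(rat["PC01", "spC"]))
})
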