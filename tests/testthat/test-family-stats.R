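test_that("the domain-type census reproduces the published percentages", {
  types <- rep(c("IV_b", "IV_c", "IV_4", "IV_p"), c(272, 102, 8, 7))
  cen <- domainTypeCensus(types)
  expect_identical(sum(cen$count), 389L)
  expect_equal(cen$percentage[cen$type == "IV_b"], 69.92)
  expect_equal(cen$percentage[cen$type == "IV_c"], 26.22)
  expect_equal(cen$percentage[cen$type == "IV_4"], 2.06)
  expect_equal(cen$percentage[cen$type == "IV_p"], 1.80)

  expect_equal(domainTypeCensus("IV_b")$percentage, 100.00)
  expect_error(domainTypeCensus(character()), "no TFs")
  ## permutation invariance
  expect_identical(domainTypeCensus(sample(types)), cen)
})

test_that("family proportions follow the printed genome-share arithmetic", {
  expect_equal(familyProportion(40, 30688), 0.13)
  expect_equal(familyProportion(38, 44853), 0.08)
})

test_that("cluster evenness requires full coverage and equal counts", {
  mkCl <- function(id, counts) {
    methods::new("GeneCluster", pcId = id,
                 members = paste0(id, "_", seq_len(sum(counts))),
                 speciesCounts = counts, support = 99, subfamily = "I")
  }
  sp7 <- paste0("sp", 1:7)
  even <- lapply(1:11, function(i)
    mkCl(sprintf("PC%02d", i), setNames(rep(1L, 7), sp7)))
  uneven <- lapply(12:20, function(i)
    mkCl(sprintf("PC%02d", i), setNames(c(2L, rep(1L, 6)), sp7)))
  fiveSp <- mkCl("PC21", setNames(rep(1L, 5), sp7[1:5]))
  ev <- pcEvenness(c(even, uneven, list(fiveSp)), sp7)
  expect_identical(ev$n_even, 11L)
  expect_identical(ev$n_total, 21L)
  expect_equal(ev$percentage, 52.38)

  allEven <- pcEvenness(even, sp7)
  expect_equal(allEven$percentage, 100.00)
  expect_error(pcEvenness(list(), sp7), "no clusters")
})

test_that("chromosome distribution pools unplaced genes and scales density", {
  mkG <- function(id, chrom, placed = TRUE)
    methods::new("GeneModel", geneId = id, species = "s", chromosome = chrom,
                 strand = "+", placed = placed, transcripts = list())
  genes <- c(lapply(1:20, function(i) mkG(paste0("g", i), "Chr01")),
             lapply(21:38, function(i) mkG(paste0("g", i), "Chr02")),
             list(mkG("g39", "scaffold_9", placed = FALSE)))
  lens <- c(Chr01 = 2e6, Chr02 = 1e6)
  d <- chromosomeDistribution(genes, lens)
  expect_identical(d$count[d$chromosome == "ChrUn"], 1L)
  expect_identical(sum(d$count), 39L)
  ## 20 genes / 2 Mb = 10; 18 genes / 1 Mb = 18
  expect_equal(d$density_per_mb[d$chromosome == "Chr01"], 10)
  expect_equal(d$density_per_mb[d$chromosome == "Chr02"], 18)
  expect_identical(attr(d, "extremes")$max_density, "Chr02")
  expect_identical(attr(d, "extremes")$max_count, "Chr01")

  lens3 <- c(lens, Chr03 = 1e6)
  d3 <- chromosomeDistribution(genes, lens3)
  expect_identical(d3$count[d3$chromosome == "Chr03"], 0L)
  expect_equal(d3$density_per_mb[d3$chromosome == "Chr03"], 0)

  bad <- c(genes, list(mkG("g40", "ChrZZ")))
  expect_error(chromosomeDistribution(bad, lens), "unknown chromosome")
})

test_that("species PCA standardizes, drops constants and fixes signs", {
  set.seed(17)
  x <- matrix(rnorm(7 * 5), 7, 5,
              dimnames = list(paste0("sp", 1:7), paste0("f", 1:5)))
  x <- cbind(x, const = rep(2, 7))
  expect_warning(pc <- speciesFeaturePCA(x), "constant")
  expect_identical(dim(pc$coordinates), c(7L, 2L))
  expect_equal(sum(pc$variance_fractions), 1)

  ## oracle: eigendecomposition of the standardized covariance
  xs <- scale(x[, 1:5])
  ev <- eigen(stats::cov(xs))
  expect_equal(pc$variance_fractions,
               ev$values / sum(ev$values), tolerance = 1e-9)
  for (k in 1:2) {
    v <- ev$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pc$coordinates[, k]), unname(as.vector(xs %*% v)),
                 tolerance = 1e-9)
  }

  ## duplicated species rows land on identical coordinates
  y <- x[c(1, 1, 2:6), 1:5]
  rownames(y) <- paste0("s", 1:7)
  pcy <- speciesFeaturePCA(y)
  expect_equal(pcy$coordinates[1, ], pcy$coordinates[2, ], tolerance = 1e-9)

  expect_error(speciesFeaturePCA(x[1:2, ]), "at least 3")
})

test_that("the feature table carries 19 species-level characteristics", {
  sim <- tinySim(23)
  allGenes <- unlist(sim$genesBySpecies, recursive = FALSE)
  hits <- hitsFor(sim$proteins)
  ft <- speciesFeatureTable(sim$genesBySpecies, hits)
  expect_identical(dim(ft), c(3L, 19L))
  expect_false(anyNA(ft[, setdiff(colnames(ft),
                                  c("frac_sfI", "frac_sfII", "frac_sfIII",
                                    "frac_sfIV"))]))
})

test_that("the family summary table equals generator truth column-wise", {
  sim <- tinySim(29, asProb = 0.5)
  allGenes <- unlist(sim$genesBySpecies, recursive = FALSE)
  hits <- hitsFor(sim$proteins)
  totals <- setNames(rep(30000, 3), names(sim$genesBySpecies))
  tab <- familySummary(sim$genesBySpecies, hits, genomeTotals = totals)
  tg <- sim$truth$genes
  for (sp in names(sim$genesBySpecies)) {
    row <- tab[tab$species == sp, ]
    tsp <- tg[tg$species == sp, ]
    expect_identical(row$A, nrow(tsp))
    expect_identical(row$n_tf, sum(tsp$n_isoforms))
    expect_identical(row$B, sum(tsp$n_isoforms >= 2))
    expect_equal(row$ratio, asRatio(nrow(tsp), sum(tsp$n_isoforms >= 2)))
    expect_equal(row$proportion, familyProportion(nrow(tsp), 30000))
  }
})
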