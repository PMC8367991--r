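test_that("isoform categories follow the documented precedence", {
  dom <- domainProtein()
  short <- substr(dom, 1, 20)  # no domain
  ir <- function(s, e) IRanges::IRanges(s, e)

  g <- intervalGene("g1", list(
    g1a = list(exons = ir(c(1, 200), c(100, 400)),
               cds = ir(c(10, 200), c(100, 250)), protein = dom),
    ## same CDS, different exon set, same protein -> identical_protein
    ## with the utr_only flag
    g1b = list(exons = ir(c(1, 200, 500), c(100, 400, 560)),
               cds = ir(c(10, 200), c(100, 250)), protein = dom),
    ## no domain -> domain_loss
    g1c = list(exons = ir(c(1, 200), c(100, 400)),
               cds = ir(10, 70), protein = short),
    ## different protein, still domain-bearing -> other
    g1d = list(exons = ir(c(1, 200), c(100, 400)),
               cds = ir(c(20, 200), c(100, 250)),
               protein = paste0("G", dom))))
  hits <- hitsFor(c(g1a = dom, g1b = dom, g1c = short,
                    g1d = paste0("G", dom)))
  sp <- classifyIsoforms(g, hits)
  expect_identical(sp$canonical, "g1d")  # longest protein wins
  expect_identical(unname(sp$categories[c("g1a", "g1b", "g1c")]),
                   c("other", "other", "domain_loss"))
  expect_identical(sum(sp$categories == "canonical"), 1L)

  ## with equal-length proteins the lexicographically first id is canonical
  g2 <- intervalGene("g2", list(
    g2b = list(exons = ir(1, 400), cds = ir(10, 250), protein = dom),
    g2a = list(exons = ir(c(1, 300), c(250, 400)), cds = ir(10, 250),
               protein = dom)))
  sp2 <- classifyIsoforms(g2, hitsFor(c(g2a = dom, g2b = dom)))
  expect_identical(sp2$canonical, "g2a")
  expect_identical(unname(sp2$categories["g2b"]), "identical_protein")
  expect_true(sp2$utr_only_flags[["g2b"]])
})

test_that("identical-protein forms collapse as in the multi-isoform example", {
  ## eight isoforms sharing two CDS variants, differing only in UTR/exon
  ## structure: the coding forms collapse to two distinct proteins
  ir <- function(s, e) IRanges::IRanges(s, e)
  dom <- domainProtein()
  domLong <- paste0(dom, "AAAAAA")
  isoforms <- list()
  for (i in 1:4)
    isoforms[[paste0("g3", letters[i])]] <-
      list(exons = ir(c(1, 200), c(100, 400 + 10 * i)),
           cds = ir(c(10, 210), c(100, 280)), protein = domLong)
  for (i in 5:8)
    isoforms[[paste0("g3", letters[i])]] <-
      list(exons = ir(c(1, 200), c(100, 400 + 10 * i)),
           cds = ir(c(20, 210), c(100, 280)), protein = dom)
  g <- intervalGene("g3", isoforms)
  prots <- vapply(isoforms, `[[`, character(1), "protein")
  sp <- classifyIsoforms(g, hitsFor(prots))
  expect_identical(sp$n_isoforms, 8L)
  expect_identical(length(unique(prots)), 2L)
  expect_identical(sum(sp$categories == "identical_protein"), 3L)

  ## single-isoform gene
  g1 <- proteinGene("s1", c(s1a = dom))
  sp1 <- classifyIsoforms(g1, hitsFor(c(s1a = dom)))
  expect_identical(unname(sp1$categories), "canonical")
})

test_that("coordinate-free input reports utr-only calls unavailable", {
  dom <- domainProtein()
  g <- proteinGene("p1", c(p1a = dom, p1b = dom))
  sp <- classifyIsoforms(g, hitsFor(c(p1a = dom, p1b = dom)))
  expect_false(sp$utr_only_available)
  expect_identical(unname(sp$categories["p1b"]), "identical_protein")
  expect_false(sp$utr_only_flags[["p1b"]])
})

test_that("splice ratio arithmetic matches the published census rows", {
  expect_equal(asRatio(33, 16), 48.48)
  expect_equal(asRatio(37, 0), 0.00)
  expect_equal(asRatio(39, 13), 33.33)
  expect_error(asRatio(0, 0), "no family members")
  expect_equal(avgSpliceForms(24, 7), 3.43)
  expect_equal(avgSpliceForms(14, 7), 2.00)
  expect_true(is.na(avgSpliceForms(0, 0)))

  census <- publishedCensus()
  expect_equal(genusSpliceRatio(census, exclude = "P_pruinosa"), 30.22)
  one <- data.frame(species = "x", A = 5, B = 5)
  expect_equal(genusSpliceRatio(one), 100.00)
  expect_error(genusSpliceRatio(one, exclude = "x"), "excluded")
})

test_that("genes whose isoforms all lack the domain are not members", {
  dom <- domainProtein()
  genes <- list(proteinGene("m1", c(m1a = dom, m1b = substr(dom, 1, 20))),
                proteinGene("m2", c(m2a = "MASTKLLNNN")))
  prots <- familyProteins(genes)
  hits <- hitsFor(prots)
  expect_identical(unname(isFamilyMember(genes, hits)), c(TRUE, FALSE))
  s <- speciesSpliceSummary(genes, hits)
  expect_identical(s$A, 1L)          # only m1
  expect_identical(s$n_tf, 2L)       # its domain-less form still counts
  expect_identical(s$B, 1L)
})

test_that("planted splice categories recover exactly at zero mutation", {
  sim <- tinySim(13, mutationRate = 0, asProb = 1)
  allGenes <- unlist(sim$genesBySpecies, recursive = FALSE)
  hits <- hitsFor(sim$proteins)
  iso <- sim$truth$isoforms
  for (g in allGenes) {
    sp <- classifyIsoforms(g, hits)
    tr <- iso[iso$gene_id == geneId(g), ]
    for (i in seq_len(nrow(tr))) {
      tid <- tr$transcript_id[i]
      if (tr$category[i] == "utr_only") {
        expect_identical(unname(sp$categories[tid]), "identical_protein")
        expect_true(sp$utr_only_flags[[tid]])
      } else {
        expect_identical(unname(sp$categories[tid]), tr$category[i])
      }
    }
  }
})

test_that("adding an isoform never decreases B or the isoform count", {
  dom <- domainProtein()
  base <- c(a1 = dom)
  genes1 <- list(proteinGene("g", base))
  s1 <- speciesSpliceSummary(genes1, hitsFor(base))
  grown <- c(base, a2 = paste0(dom, "A"))
  names(grown) <- c("a1", "a2")
  genes2 <- list(proteinGene("g", grown))
  s2 <- speciesSpliceSummary(genes2, hitsFor(grown))
  expect_gte(s2$B, s1$B)
  expect_gte(s2$n_tf, s1$n_tf)
})
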