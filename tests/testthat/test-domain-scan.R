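test_that("the scanner finds the canonical tetrad and records spacers", {
  p <- paste0("AA", "C", "DE", "C", strrep("A", 18), "C", "GG", "C",
              "KRKRAAAAAAAAAAA")
  h <- scanZincFinger(p, "t1")
  expect_identical(nrow(h), 1L)
  expect_identical(unlist(h[, c("s1", "s2", "s3")], use.names = FALSE),
                   c(2L, 18L, 2L))
  expect_identical(h$type, "IV_b")
  expect_equal(h$basic_fraction, 4 / 15)

  expect_identical(nrow(scanZincFinger("MASTKLL")), 0L)

  two <- paste0(domainProtein(2, 18), domainProtein(2, 20))
  h2 <- scanZincFinger(two)
  expect_identical(h2$type, c("IV_b", "IV_c"))
  expect_true(all(diff(h2$start) > 0))
})

test_that("input validation: empty errors, lowercase normalizes", {
  expect_error(scanZincFinger(""), "non-empty")
  expect_warning(h <- scanZincFinger(tolower(domainProtein())), "lowercase")
  expect_identical(nrow(h), 1L)
})

test_that("scanner equals brute-force quadruple enumeration on 500 proteins", {
  set.seed(20)
  for (i in 1:500) {
    p <- randomProtein(sample(40:400, 1))
    h <- scanZincFinger(p)
    b <- bruteZfScan(p)
    expect_identical(nrow(h), nrow(b))
    if (nrow(h)) {
      expect_identical(h$c1, as.integer(b[, 1]))
      expect_identical(h$c4, as.integer(b[, 4]))
      expect_identical(h$s2, as.integer(b[, 6]))
    }
  }
})

test_that("spacing triples map to the named domain types", {
  expect_identical(classifyDomainType(c(2, 17, 2)), "IV_a")
  expect_identical(classifyDomainType(c(2, 18, 2)), "IV_b")
  expect_identical(classifyDomainType(c(2, 20, 2)), "IV_c")
  expect_identical(classifyDomainType(c(4, 18, 2)), "IV_4")
  expect_identical(classifyDomainType(c(2, 19, 2)), "IV_other(2,19,2)")
  expect_error(classifyDomainType(c(1, 18, 2)), "out of scanner bounds")
  expect_error(classifyDomainType(c(2, 21, 2)), "out of scanner bounds")
})

test_that("terminal class splits at the midpoint with a strict-less rule", {
  expect_identical(terminalClass(list(start = 25, end = 35), 300), "N")
  expect_identical(terminalClass(list(start = 245, end = 255), 300), "C")
  expect_identical(terminalClass(list(start = 145, end = 155), 300), "C")
  expect_error(terminalClass(list(start = 1, end = 5), 0), "zero-length")
})

test_that("basic-region fraction truncates its denominator", {
  p <- paste0(domainProtein(cflank = 0), "")  # ends KRKR after C4
  h <- scanZincFinger(p)
  expect_equal(basicRegionFraction(p, h[1, ], 15), 1)   # 4 of 4 available
  pAla <- paste0(substr(p, 1, h$c4), strrep("A", 20))
  expect_equal(basicRegionFraction(pAla, h[1, ], 15), 0)
  pEnd <- substr(p, 1, h$c4)
  expect_true(is.na(basicRegionFraction(pEnd, h[1, ], 15)))
})

test_that("profile: identical references self-score at the maximum", {
  refs <- rep("CSNCTLDGHYWAREGKNGQPSDCNAC", 5)
  prof <- buildDomainProfile(refs, pseudocount = 1)
  scores <- vapply(refs, profileScore, numeric(1), profile = prof)
  expect_true(all(abs(scores - max(scores)) < 1e-12))

  withGap <- c(refs, "CSNCTLDGHYWAREGKNGQPSDCNAC")
  allGap <- vapply(strsplit(withGap, ""), function(x) {
    x[5] <- "-"; paste(x, collapse = "")
  }, character(1))
  expect_warning(p2 <- buildDomainProfile(allGap), "all-gap")
  expect_identical(nrow(p2@logOdds), nchar(refs[1]) - 1L)

  expect_error(buildDomainProfile(refs[1:4]), "at least 5")
})

test_that("shuffled sequences rarely reach the profile threshold", {
  set.seed(1)
  refs <- replicate(8, mutateSequence("CSNCTLDGHYWAREGKNGQPSDCNAC", 0.08,
                                      protected = c(1, 4, 23, 26)))
  prof <- buildDomainProfile(refs)
  below <- 0L
  for (i in 1:100) {
    shuf <- paste(sample(strsplit(refs[1], "")[[1]]), collapse = "")
    if (profileScore(shuf, prof) <= prof@threshold) below <- below + 1L
  }
  expect_gte(below, 95L)
})

test_that("partial-domain calls: degraded tetrad in, complete hit wins", {
  set.seed(2)
  refs <- replicate(8, mutateSequence("CSNCTLDGHYWAREGKNGQPSDCNAC", 0.08,
                                      protected = c(1, 4, 23, 26)))
  prof <- buildDomainProfile(refs)
  p <- paste0(strrep("A", 12), refs[1], strrep("G", 12))
  expect_identical(nrow(scanPartialDomains(p, prof)), 0L)

  h <- scanZincFinger(p)
  deg <- degradeToPartial(p, h[1, ], which = 4)
  hp <- scanPartialDomains(deg, prof)
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$type, "IV_p")
  expect_true(hp$score >= prof@threshold)

  ## random same-composition sequences: no call in >= 95/100 trials
  set.seed(1)
  none <- 0L
  for (i in 1:100) {
    r <- paste(sample(strsplit(deg, "")[[1]]), collapse = "")
    if (nrow(scanPartialDomains(r, prof)) == 0L) none <- none + 1L
  }
  expect_gte(none, 95L)
})

test_that("type census conserves the total hit count", {
  set.seed(3)
  prots <- c(a = domainProtein(2, 18), b = domainProtein(2, 20),
             c = domainProtein(4, 18), d = domainProtein(2, 17),
             e = "MNOPE")
  prots["e"] <- "MASTKL"
  hits <- hitsFor(prots)
  total <- sum(vapply(hits, nrow, integer(1)))
  types <- representativeTypes(hits)
  expect_identical(length(types), sum(vapply(hits, nrow, integer(1)) > 0))
  census <- domainTypeCensus(types)
  expect_identical(sum(census$count), total)
})

test_that("planted types recover perfectly without mutation", {
  sim <- tinySim(5, mutationRate = 0, asProb = 0)
  hits <- hitsFor(sim$proteins)
  types <- representativeTypes(hits)
  tg <- sim$truth$genes
  expect_identical(unname(types[paste0(tg$gene_id, "a")]), tg$type)
})
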