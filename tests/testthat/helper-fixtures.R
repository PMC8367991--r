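## shared fixtures and independent oracles, all built in code

AA <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

## write a minimal one-gene GFF3 + genome FASTA; cdsSeq is given in sense
## orientation and embedded (reverse-complemented on "-") at offset
writeToyGene <- function(dir, cdsSeq, strand = "+", chrom = "Chr01",
                         exonSplit = NULL, utr5 = 5L, utr3 = 4L) {
  n <- nchar(cdsSeq)
  lead <- 10L
  sense <- paste0(strrep("T", lead + utr5), cdsSeq, strrep("G", utr3),
                  strrep("T", 8))
  L <- nchar(sense)
  genome <- if (strand == "+") sense else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
  ## sense-local coordinates
  cdsLocal <- IRanges::IRanges(lead + utr5 + 1L, lead + utr5 + n)
  exLocal <- IRanges::IRanges(lead + 1L, lead + utr5 + n + utr3)
  if (!is.null(exonSplit)) {
    ## split the single exon/CDS at a sense-local position (intron-free toy
    ## split: two abutting features)
    s <- exonSplit
    cdsLocal <- IRanges::IRanges(
      c(IRanges::start(cdsLocal), s + 1L), c(s, IRanges::end(cdsLocal)))
    exLocal <- IRanges::IRanges(
      c(IRanges::start(exLocal), s + 1L), c(s, IRanges::end(exLocal)))
  }
  flip <- function(r) IRanges::IRanges(L - IRanges::end(r) + 1L,
                                       L - IRanges::start(r) + 1L)
  cdsG <- if (strand == "+") cdsLocal else flip(cdsLocal)
  exG <- if (strand == "+") exLocal else flip(exLocal)
  o <- order(IRanges::start(exG)); exG <- exG[o]
  o <- order(IRanges::start(cdsG)); cdsG <- cdsG[o]

  gff <- file.path(dir, "toy.gff3"); fa <- file.path(dir, "toy.fa")
  rows <- c("##gff-version 3",
    sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=g1", chrom,
            min(IRanges::start(exG)), max(IRanges::end(exG)), strand),
    sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=g1a;Parent=g1", chrom,
            min(IRanges::start(exG)), max(IRanges::end(exG)), strand),
    sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=g1a.e%d;Parent=g1a", chrom,
            IRanges::start(exG), IRanges::end(exG), strand,
            seq_along(exG)),
    sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=g1a.c%d;Parent=g1a", chrom,
            IRanges::start(cdsG), IRanges::end(cdsG), strand,
            seq_along(cdsG)))
  writeLines(rows, gff)
  writeLines(c(paste0(">", chrom), genome), fa)
  list(gff3 = gff, fasta = fa)
}

## independent translation oracle: plain codon-table lookup
bruteTranslate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  cods <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  aa <- unname(gc[cods])
  sub("\\*$", "", paste(aa, collapse = ""))
}

bruteRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## independent zinc-finger scan: enumerate all cysteine quadruples within
## the spacing bounds, then apply the documented tie-break greedily
bruteZfScan <- function(protein) {
  cp <- which(strsplit(protein, "")[[1]] == "C")
  cand <- list()
  for (a in cp) for (b in cp[cp > a]) for (cc in cp[cp > b])
    for (d in cp[cp > cc]) {
      s <- c(b - a - 1L, cc - b - 1L, d - cc - 1L)
      if (s[1] >= 2 && s[1] <= 4 && s[2] >= 17 && s[2] <= 20 && s[3] == 2)
        cand[[length(cand) + 1L]] <- c(a, b, cc, d, s)
    }
  if (!length(cand)) return(matrix(numeric(0), 0, 7))
  m <- do.call(rbind, cand)
  m <- m[order(m[, 1], m[, 5], m[, 6]), , drop = FALSE]
  picked <- NULL
  while (nrow(m)) {
    picked <- rbind(picked, m[1, ])
    m <- m[m[, 1] > picked[nrow(picked), 4], , drop = FALSE]
  }
  picked[order(picked[, 1]), , drop = FALSE]
}

## random protein with enough cysteines to exercise the scanner
randomProtein <- function(len, cWeight = 4) {
  w <- rep(1, 20); w[AA == "C"] <- cWeight
  paste(sample(AA, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

## deterministic small simulation for module tests
tinySim <- function(seed, ...) {
  makeFamily(simConfig(seed = seed, nSpecies = 3L, nClusters = 4L,
                       clusterCopies = 1L,
                       clusterSubfamilies = c("III", "I", "II", "IV"),
                       nSpeciesSpecific = 0L, ...))
}

## construct a bare GeneModel from protein strings (no coordinates)
proteinGene <- function(gid, prots, species = "spX") {
  txs <- lapply(names(prots), function(tid)
    methods::new("TranscriptModel", transcriptId = tid,
                 protein = prots[[tid]], status = "ok"))
  methods::new("GeneModel", geneId = gid, species = species,
               chromosome = "un", strand = "+", placed = FALSE,
               transcripts = txs)
}

## a coordinate gene with configurable isoform interval sets
intervalGene <- function(gid, isoforms, species = "spX", chrom = "Chr01") {
  txs <- lapply(names(isoforms), function(tid) {
    iso <- isoforms[[tid]]
    methods::new("TranscriptModel", transcriptId = tid,
                 exons = iso$exons, cds = iso$cds,
                 protein = iso$protein, status = "ok")
  })
  methods::new("GeneModel", geneId = gid, species = species,
               chromosome = chrom, strand = "+", placed = TRUE,
               transcripts = txs)
}

## hits list for proteins via the package scanner (convenience)
hitsFor <- function(prots) {
  out <- lapply(names(prots), function(id) scanZincFinger(prots[[id]], id))
  names(out) <- names(prots)
  out
}

## one valid complete-domain protein with given spacers
domainProtein <- function(s1 = 2, s2 = 18, nflank = 30, cflank = 30,
                          s1res = NULL, s2res = NULL) {
  s1res <- if (is.null(s1res)) strrep("S", s1) else s1res
  s2res <- if (is.null(s2res)) paste(rep(c("T","L","D","G","H"),
                                         length.out = s2), collapse = "")
           else s2res
  paste0(strrep("A", nflank), "C", s1res, "C", s2res, "C", "NA", "C",
         "KRKR", strrep("A", cflank))
}
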