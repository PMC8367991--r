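#' @importFrom Biostrings readDNAStringSet readAAStringSet DNAString
#'   DNAStringSet AAStringSet translate reverseComplement subseq
#'   writeXStringSet GENETIC_CODE
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

## ---------------------------------------------------------------------------
## genome_io: GFF3 + genome FASTA -> GeneModel set; protein-only FASTA loader;
## GFF3 writer for round-trips.
## ---------------------------------------------------------------------------

#' Parse an annotated genome into gene models
#'
#' Reads a GFF3 gene annotation and its genome FASTA, derives each
#' transcript's protein by strand-aware CDS extraction and translation under
#' the standard nuclear code, and flags genes on unassigned scaffolds.
#'
#' Transcripts whose concatenated CDS length is not a multiple of three, or
#' whose translation contains an internal stop, are flagged `"malformed"`
#' (kept, but excluded from all downstream analyses) with a warning.
#' Transcripts without CDS are kept as `"noncoding"` isoforms. A CDS that
#' references a sequence absent from the FASTA is a hard error.
#'
#' @param gff3Path path to a GFF3 file with gene / mRNA (or transcript) /
#'   exon / CDS features.
#' @param fastaPath path to the matching genome FASTA.
#' @param species species tag stored on every gene.
#' @param unplacedPattern glob matched against sequence names; genes on
#'   matching sequences get `placed = FALSE` and are pooled as `"ChrUn"` in
#'   chromosome reports. Default `"scaffold_*"`.
#' @return named list of [GeneModel-class] objects (one per gene feature).
#' @export
readGenomeAnnotation <- function(gff3Path, fastaPath, species = "species1",
                                 unplacedPattern = "scaffold_*") {
  gff <- rtracklayer::import(gff3Path, format = "gff3")
  genome <- readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))

  type <- as.character(gff$type)
  ids  <- as.character(gff$ID)
  par  <- vapply(as.list(gff$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  geneIdx <- which(type == "gene")
  txIdx   <- which(type %in% c("mRNA", "transcript"))
  unplRx  <- utils::glob2rx(unplacedPattern)

  ## group exon/CDS rows by parent transcript
  childIdx <- which(type %in% c("exon", "CDS"))
  byParent <- split(childIdx, par[childIdx])

  genes <- list()
  for (gi in geneIdx) {
    gid <- ids[gi]
    chrom <- as.character(GenomicRanges::seqnames(gff)[gi])
    strand <- as.character(BiocGenerics::strand(gff)[gi])
    if (!strand %in% c("+", "-")) strand <- "+"
    txs <- list()
    for (ti in txIdx[par[txIdx] == gid]) {
      tid <- ids[ti]
      kids <- byParent[[tid]]
      exR <- sortRanges(grRanges(gff)[kids[type[kids] == "exon"]])
      cdR <- sortRanges(grRanges(gff)[kids[type[kids] == "CDS"]])
      if (length(exR) == 0L) exR <- cdR  # CDS-only annotations
      tx <- buildTranscript(tid, exR, cdR, strand, chrom, genome)
      txs[[tid]] <- tx
    }
    genes[[gid]] <- methods::new("GeneModel",
      geneId = gid, species = species, chromosome = chrom, strand = strand,
      placed = !grepl(unplRx, chrom), transcripts = unname(txs))
  }
  genes
}

grRanges <- function(gr) {
  IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr))
}

## assemble one TranscriptModel: derive UTRs, extract + translate CDS
buildTranscript <- function(tid, exR, cdR, strand, chrom, genome) {
  if (length(cdR) == 0L) {
    return(methods::new("TranscriptModel", transcriptId = tid, exons = exR,
                        status = "noncoding"))
  }
  if (!chrom %in% names(genome))
    stop("CDS of transcript '", tid, "' references missing sequence '",
         chrom, "'")
  ## UTRs: exon coverage outside the CDS span, sided by strand
  cdsSpan <- range(cdR)
  left  <- IRanges::restrict(exR, end = IRanges::start(cdsSpan) - 1L)
  right <- IRanges::restrict(exR, start = IRanges::end(cdsSpan) + 1L)
  if (strand == "+") { u5 <- left; u3 <- right } else { u5 <- right; u3 <- left }

  chromSeq <- genome[[chrom]]
  pieces <- lapply(seq_along(cdR), function(i)
    subseq(chromSeq, IRanges::start(cdR)[i], IRanges::end(cdR)[i]))
  cdsSeq <- do.call(Biostrings::xscat, pieces)
  if (strand == "-") cdsSeq <- reverseComplement(cdsSeq)

  if (length(cdsSeq) %% 3L != 0L) {
    warning("transcript '", tid, "' has CDS length not divisible by 3; ",
            "flagged malformed")
    return(methods::new("TranscriptModel", transcriptId = tid, exons = exR,
                        cds = cdR, utr5 = u5, utr3 = u3, status = "malformed"))
  }
  prot <- as.character(suppressWarnings(translate(cdsSeq)))
  prot <- sub("\\*$", "", prot)
  if (grepl("\\*", prot)) {
    warning("transcript '", tid, "' translates with an internal stop; ",
            "flagged malformed")
    return(methods::new("TranscriptModel", transcriptId = tid, exons = exR,
                        cds = cdR, utr5 = u5, utr3 = u3, status = "malformed"))
  }
  methods::new("TranscriptModel", transcriptId = tid, exons = exR, cds = cdR,
               utr5 = u5, utr3 = u3, protein = prot, status = "ok")
}

#' Load a pre-translated proteome as coordinate-free gene models
#'
#' FASTA headers must encode gene and isoform identity through a regular
#' expression with two capture groups (gene id, isoform tag); the default
#' expects a trailing lowercase isoform letter, the common `GATA6a`,
#' `GATA6b`, ... convention. Headers that do not match are skipped with a
#' warning; duplicated transcript ids are an error. Coordinate-dependent
#' analyses (UTR-only splice calls, chromosome maps) are unavailable on
#' models loaded this way.
#'
#' @param fastaPath protein FASTA path.
#' @param idPattern regex with two capture groups over the first header
#'   word. Default `"^(.*[^a-z])([a-z])$"`.
#' @param species species tag.
#' @return named list of [GeneModel-class] (chromosome `"un"`,
#'   `placed = FALSE`).
#' @export
readProteome <- function(fastaPath, idPattern = "^(.*[^a-z])([a-z])$",
                         species = "species1") {
  aa <- readAAStringSet(fastaPath)
  if (length(aa) == 0L) {
    warning("empty protein FASTA: ", fastaPath)
    return(list())
  }
  hdr <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(hdr))
    stop("duplicate transcript id(s) in FASTA: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ","))
  ok <- grepl(idPattern, hdr)
  if (any(!ok))
    warning("headers not matching the id rule were skipped: ",
            paste(hdr[!ok], collapse = ","))
  genesOf <- sub(idPattern, "\\1", hdr[ok])
  genes <- list()
  for (gid in unique(genesOf)) {
    sel <- which(ok)[genesOf == gid]
    txs <- lapply(sel, function(i)
      methods::new("TranscriptModel", transcriptId = hdr[i],
                   protein = sub("\\*$", "", as.character(aa[[i]])),
                   status = "ok"))
    genes[[gid]] <- methods::new("GeneModel", geneId = gid, species = species,
                                 chromosome = "un", strand = "+",
                                 placed = FALSE, transcripts = txs)
  }
  genes
}

#' Write gene models back to GFF3
#'
#' Emits gene / mRNA / exon / CDS (and derived UTR) features, 1-based
#' inclusive, suitable for re-parsing with [readGenomeAnnotation()].
#'
#' @param genes list of [GeneModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGFF3 <- function(genes, path) {
  rows <- list()
  add <- function(chrom, type, r, strand, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = chrom, source = "gatafam", type = type,
      start = IRanges::start(r), end = IRanges::end(r), score = ".",
      strand = strand, phase = if (type == "CDS") "0" else ".",
      attributes = attrs, stringsAsFactors = FALSE)
  }
  for (g in genes) {
    span <- range(do.call(c, lapply(g@transcripts, function(t)
      if (length(t@exons)) t@exons else t@cds)))
    add(g@chromosome, "gene", span, g@strand, paste0("ID=", g@geneId))
    for (t in g@transcripts) {
      add(g@chromosome, "mRNA", range(if (length(t@exons)) t@exons else t@cds),
          g@strand, paste0("ID=", t@transcriptId, ";Parent=", g@geneId))
      if (length(t@exons))
        add(g@chromosome, "exon", t@exons, g@strand,
            paste0("ID=", t@transcriptId, ".exon", seq_along(t@exons),
                   ";Parent=", t@transcriptId))
      if (length(t@cds))
        add(g@chromosome, "CDS", t@cds, g@strand,
            paste0("ID=", t@transcriptId, ".cds", seq_along(t@cds),
                   ";Parent=", t@transcriptId))
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' All coding proteins of a gene-model set
#'
#' @param genes list of [GeneModel-class].
#' @return named character vector, one entry per coding isoform
#'   (names are transcript ids).
#' @export
familyProteins <- function(genes) {
  out <- character()
  for (g in genes)
    for (t in codingTranscripts(g)) out[t@transcriptId] <- t@protein
  out
}
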