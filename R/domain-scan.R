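## ---------------------------------------------------------------------------
## domain_scan: class-IV zinc-finger detection and typing.
##
## The DNA-binding domain of a GATA TF is the C-X(2-4)-C-X(17-20)-C-X(2)-C
## tetrad followed by a basic region. Complete domains are found by
## exhaustive cysteine-quadruple matching with a deterministic overlap rule;
## partial (IV_p) domains are called with a log-odds profile.
## ---------------------------------------------------------------------------

SPACER_BOUNDS <- list(s1 = c(2L, 4L), s2 = c(17L, 20L), s3 = c(2L, 2L))

#' Scan a protein for complete class-IV zinc-finger domains
#'
#' Finds all matches of `C X(2-4) C X(17-20) C X(2) C`. Candidate cysteine
#' quadruples that overlap are resolved deterministically: leftmost C1 first,
#' then the shortest first spacer, then the shortest second spacer; the
#' survivor suppresses every candidate overlapping its span, and scanning
#' proceeds to the right. `X` never matches a cysteine position.
#'
#' @param protein single uppercase amino-acid string (lowercase is
#'   normalized with a warning).
#' @param proteinId id recorded on the hits.
#' @param basicWindow window length for [basicRegionFraction()] annotation.
#' @return data.frame with one row per hit: `protein_id`, `c1..c4`
#'   (1-based cysteine positions), `s1,s2,s3` spacers, `type`, `start`,
#'   `end` (1-based inclusive span), `score` (NA for pattern hits),
#'   `terminal`, `basic_fraction`.
#' @export
scanZincFinger <- function(protein, proteinId = "protein", basicWindow = 15L) {
  protein <- normalizeProtein(protein)
  cand <- zfCandidates(protein)
  picked <- resolveOverlaps(cand)
  hits <- emptyHits()
  if (nrow(picked)) {
    n <- nchar(protein)
    hits <- data.frame(
      protein_id = proteinId,
      c1 = picked$c1, c2 = picked$c2, c3 = picked$c3, c4 = picked$c4,
      s1 = picked$s1, s2 = picked$s2, s3 = picked$s3,
      type = vapply(seq_len(nrow(picked)), function(i)
        classifyDomainType(c(picked$s1[i], picked$s2[i], picked$s3[i])),
        character(1)),
      start = picked$c1, end = picked$c4,
      score = NA_real_,
      stringsAsFactors = FALSE)
    hits$terminal <- vapply(seq_len(nrow(hits)), function(i)
      terminalClass(hits[i, ], n), character(1))
    hits$basic_fraction <- vapply(seq_len(nrow(hits)), function(i)
      basicRegionFraction(protein, hits[i, ], basicWindow), numeric(1))
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

emptyHits <- function() {
  data.frame(protein_id = character(), c1 = integer(), c2 = integer(),
             c3 = integer(), c4 = integer(), s1 = integer(), s2 = integer(),
             s3 = integer(), type = character(), start = integer(),
             end = integer(), score = numeric(), terminal = character(),
             basic_fraction = numeric(), stringsAsFactors = FALSE)
}

## all cysteine quadruples satisfying the spacing bounds
zfCandidates <- function(protein) {
  cpos <- which(strsplit(protein, "")[[1]] == "C")
  out <- list()
  for (a in cpos) {
    for (b in cpos[cpos > a]) {
      s1 <- b - a - 1L
      if (s1 < SPACER_BOUNDS$s1[1] || s1 > SPACER_BOUNDS$s1[2]) next
      for (cc in cpos[cpos > b]) {
        s2 <- cc - b - 1L
        if (s2 < SPACER_BOUNDS$s2[1] || s2 > SPACER_BOUNDS$s2[2]) next
        for (d in cpos[cpos > cc]) {
          s3 <- d - cc - 1L
          if (s3 != SPACER_BOUNDS$s3[1]) next
          out[[length(out) + 1L]] <-
            c(c1 = a, c2 = b, c3 = cc, c4 = d, s1 = s1, s2 = s2, s3 = s3)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(c1 = integer(), c2 = integer(), c3 = integer(),
                      c4 = integer(), s1 = integer(), s2 = integer(),
                      s3 = integer()))
  as.data.frame(do.call(rbind, out))
}

## deterministic overlap resolution: leftmost C1, then min s1, then min s2
resolveOverlaps <- function(cand) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$c1, cand$s1, cand$s2), , drop = FALSE]
  picked <- cand[0, , drop = FALSE]
  repeat {
    if (!nrow(cand)) break
    top <- cand[1, , drop = FALSE]
    picked <- rbind(picked, top)
    cand <- cand[cand$c1 > top$c4, , drop = FALSE]
  }
  picked
}

#' Type a complete domain by its inter-cysteine spacing
#'
#' `(2,17,2)` is IV_a, `(2,18,2)` IV_b, `(2,20,2)` IV_c, `(4,18,2)` IV_4;
#' any other in-bounds triple is reported as `IV_other(s1,s2,s3)`.
#'
#' @param spacers integer vector `c(s1, s2, s3)`.
#' @return type label string.
#' @export
classifyDomainType <- function(spacers) {
  stopifnot(length(spacers) == 3L)
  s <- as.integer(spacers)
  if (s[1] < SPACER_BOUNDS$s1[1] || s[1] > SPACER_BOUNDS$s1[2] ||
      s[2] < SPACER_BOUNDS$s2[1] || s[2] > SPACER_BOUNDS$s2[2] ||
      s[3] != SPACER_BOUNDS$s3[1])
    stop("spacers out of scanner bounds: ", paste(s, collapse = ","))
  key <- paste(s, collapse = ",")
  switch(key,
         "2,17,2" = "IV_a",
         "2,18,2" = "IV_b",
         "2,20,2" = "IV_c",
         "4,18,2" = "IV_4",
         sprintf("IV_other(%d,%d,%d)", s[1], s[2], s[3]))
}

#' N/C-terminal placement of a domain
#'
#' Domains of subfamilies I--III sit near the C-terminus while subfamily-IV
#' domains are N-terminal; the class is the side of the protein holding the
#' domain midpoint (`N` if midpoint/length < threshold, else `C`).
#'
#' @param hit one hit row (needs `start`, `end`).
#' @param proteinLength protein length in residues.
#' @param threshold fractional cut point, default 0.5; exact threshold goes
#'   to `C` (strict-less rule).
#' @return `"N"` or `"C"`.
#' @export
terminalClass <- function(hit, proteinLength, threshold = 0.5) {
  if (proteinLength <= 0L) stop("zero-length protein")
  if (proteinLength < hit$end) stop("hit extends beyond protein")
  mid <- (hit$start + hit$end) / 2
  if (mid / proteinLength < threshold) "N" else "C"
}

#' Fraction of basic residues downstream of the domain
#'
#' The zinc finger is followed by a lysine/arginine-rich basic region that
#' contributes to DNA binding. Reported as an annotation only; it is never
#' used to filter hits.
#'
#' @param protein protein string.
#' @param hit one hit row (needs `c4`).
#' @param window residues inspected after C4 (denominator truncates to the
#'   residues actually available).
#' @return fraction of K/R, or `NA` if no residues follow C4.
#' @export
basicRegionFraction <- function(protein, hit, window = 15L) {
  n <- nchar(protein)
  from <- hit$c4 + 1L
  if (from > n) return(NA_real_)
  to <- min(n, hit$c4 + window)
  seg <- strsplit(substr(protein, from, to), "")[[1]]
  sum(seg %in% c("K", "R")) / length(seg)
}

#' Build a log-odds profile from aligned complete domains
#'
#' Laplace-smoothed per-position residue frequencies are scored against the
#' background composition of the reference set. The calling threshold
#' defaults to the minimum self-score of the references minus `margin`.
#' Columns that are all-gap are dropped with a warning. Residues outside the
#' 20-letter alphabet (e.g. `X`) score the background-weighted position mean.
#'
#' @param referenceDomains character vector of aligned domain strings
#'   (equal length, gaps `-` or `.`), at least 5.
#' @param pseudocount Laplace pseudocount (default 1).
#' @param margin subtracted from the minimum reference self-score to set the
#'   calling threshold (default 1).
#' @return [DomainProfile-class].
#' @export
buildDomainProfile <- function(referenceDomains, pseudocount = 1,
                               margin = 1) {
  if (length(referenceDomains) < 5L)
    stop("need at least 5 reference domains")
  refs <- toupper(gsub("\\.", "-", referenceDomains))
  if (length(unique(nchar(refs))) != 1L)
    stop("reference domains must be aligned to equal length")
  m <- do.call(rbind, strsplit(refs, ""))
  allGap <- apply(m, 2, function(col) all(col == "-"))
  if (any(allGap)) {
    warning("dropping ", sum(allGap), " all-gap column(s)")
    m <- m[, !allGap, drop = FALSE]
  }
  L <- ncol(m)
  res <- m[m %in% AA20]
  bg <- (table(factor(res, levels = AA20)) + pseudocount) /
    (length(res) + 20 * pseudocount)
  bg <- as.numeric(bg)
  lo <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    cnt <- table(factor(m[, j][m[, j] %in% AA20], levels = AA20))
    p <- (as.numeric(cnt) + pseudocount) / (sum(cnt) + 20 * pseudocount)
    lo[j, ] <- log(p / bg)
    ## renormalize exactly against the background so the validity contract
    ## sum_a bg_a * exp(lo_a) == 1 holds to numerical precision
    lo[j, ] <- lo[j, ] - log(sum(bg * exp(lo[j, ])))
  }
  prof <- methods::new("DomainProfile", logOdds = lo, background = bg,
                       threshold = 0)
  self <- vapply(seq_len(nrow(m)), function(i)
    scoreWindowRow(m[i, ], prof), numeric(1))
  prof@threshold <- min(self) - margin
  prof
}

## score one aligned row (character vector) against the profile
scoreWindowRow <- function(chars, profile) {
  lo <- profile@logOdds
  bg <- profile@background
  s <- 0
  for (j in seq_len(nrow(lo))) {
    ch <- chars[j]
    if (ch %in% AA20) s <- s + lo[j, ch]
    else if (ch != "-") s <- s + sum(bg * lo[j, ])  # X etc: background mean
    ## gaps contribute 0
  }
  s
}

#' Profile score of an ungapped window
#'
#' @param window amino-acid string whose length equals the profile length.
#' @param profile a [DomainProfile-class].
#' @return log-odds score.
#' @export
profileScore <- function(window, profile) {
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != nrow(profile@logOdds))
    stop("window length does not match profile length")
  scoreWindowRow(chars, profile)
}

#' Call partial (IV_p) domains with a profile
#'
#' Slides the profile along the protein; windows scoring at or above the
#' profile threshold but lacking the complete cysteine tetrad are emitted as
#' `IV_p` hits. Windows overlapping a complete hit from [scanZincFinger()]
#' are suppressed (the complete call wins). Overlapping qualifying windows
#' are reduced to the best-scoring one (leftmost on ties).
#'
#' @param protein protein string.
#' @param profile [DomainProfile-class].
#' @param proteinId id recorded on hits.
#' @param completeHits optional precomputed [scanZincFinger()] result.
#' @return data.frame in the same layout as [scanZincFinger()]; cysteine
#'   position columns are `NA` where the tetrad is incomplete.
#' @export
scanPartialDomains <- function(protein, profile, proteinId = "protein",
                               completeHits = NULL) {
  protein <- normalizeProtein(protein)
  if (is.null(completeHits))
    completeHits <- scanZincFinger(protein, proteinId)
  L <- nrow(profile@logOdds)
  n <- nchar(protein)
  hits <- emptyHits()
  if (n < L) return(hits)
  chars <- strsplit(protein, "")[[1]]
  scores <- vapply(seq_len(n - L + 1L), function(i)
    scoreWindowRow(chars[i:(i + L - 1L)], profile), numeric(1))
  ok <- which(scores >= profile@threshold)
  ## complete-call precedence
  if (nrow(completeHits) && length(ok)) {
    keep <- vapply(ok, function(i)
      !any(i <= completeHits$end & (i + L - 1L) >= completeHits$start),
      logical(1))
    ok <- ok[keep]
  }
  ## greedy best-score (then leftmost) non-overlap reduction
  ok <- ok[order(-scores[ok], ok)]
  sel <- integer()
  for (i in ok)
    if (!any(abs(i - sel) < L)) sel <- c(sel, i)
  for (i in sort(sel)) {
    win <- chars[i:(i + L - 1L)]
    cand <- zfCandidates(paste(win, collapse = ""))
    if (nrow(cand)) next  # complete tetrad inside the window: not partial
    hits <- rbind(hits, data.frame(
      protein_id = proteinId, c1 = NA_integer_, c2 = NA_integer_,
      c3 = NA_integer_, c4 = NA_integer_, s1 = NA_integer_,
      s2 = NA_integer_, s3 = NA_integer_, type = "IV_p",
      start = i, end = i + L - 1L, score = scores[i],
      terminal = if (((i + i + L - 1L) / 2) / n < 0.5) "N" else "C",
      basic_fraction = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(hits) <- NULL
  hits
}

#' Scan every coding isoform of a gene-model set
#'
#' Complete domains always; IV_p calls when a profile is supplied.
#'
#' @param genes list of [GeneModel-class].
#' @param profile optional [DomainProfile-class] for IV_p calling.
#' @return named list of hit data.frames, one per coding isoform (possibly
#'   zero-row).
#' @export
scanFamily <- function(genes, profile = NULL) {
  prots <- familyProteins(genes)
  out <- vector("list", length(prots))
  names(out) <- names(prots)
  for (id in names(prots)) {
    h <- scanZincFinger(prots[[id]], id)
    if (!is.null(profile)) {
      hp <- scanPartialDomains(prots[[id]], profile, id, completeHits = h)
      h <- rbind(h, hp)
    }
    out[[id]] <- h
  }
  out
}

#' Does an isoform carry at least one domain hit?
#' @param hits data.frame of hits for one isoform.
#' @param includePartial count IV_p hits as domain-bearing (default TRUE).
#' @return logical.
#' @export
isDomainBearing <- function(hits, includePartial = TRUE) {
  if (!nrow(hits)) return(FALSE)
  if (includePartial) TRUE else any(hits$type != "IV_p")
}
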