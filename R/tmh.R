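## ---------------------------------------------------------------------------
## tmh_scan: sliding-window Kyte-Doolittle hydropathy as a documented
## stand-in transmembrane-helix predictor, plus an import path for
## externally produced TMH span tables.
## ---------------------------------------------------------------------------

#' Kyte-Doolittle hydropathy profile
#'
#' Centered moving average of the Kyte-Doolittle index over an odd window.
#' Ends are truncated: positions without a full window are `NA`.
#'
#' @param protein amino-acid string, length >= `window`.
#' @param window odd window size (default 19).
#' @return numeric vector along the protein (`NA` at the truncated ends).
#' @export
hydropathyProfile <- function(protein, window = 19L) {
  protein <- normalizeProtein(protein)
  n <- nchar(protein)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > n) stop("window exceeds protein length")
  vals <- KD_INDEX[strsplit(protein, "")[[1]]]
  vals[is.na(vals)] <- 0  # X and other ambiguity codes are neutral
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  cs <- cumsum(c(0, vals))
  centers <- (half + 1L):(n - half)
  out[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  out
}

#' Predict transmembrane helices from a hydropathy profile
#'
#' Maximal runs of positions with mean hydropathy at or above `threshold`
#' and run length at least `minLen`. A hydropathy-window predictor is a
#' deliberately simple stand-in for HMM-based TMH predictors; spans from an
#' external predictor can be supplied instead via [readTmhTable()].
#'
#' @param profile vector from [hydropathyProfile()].
#' @param threshold minimum windowed hydropathy (default 1.6).
#' @param minLen minimum run length in residues (default 15).
#' @return data.frame `start`, `end`, `mean_hydropathy` (possibly 0 rows).
#' @export
predictTmh <- function(profile, threshold = 1.6, minLen = 15L) {
  hot <- !is.na(profile) & profile >= threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  data.frame(start = starts[keep], end = ends[keep],
             mean_hydropathy = vapply(which(keep), function(i)
               mean(profile[starts[i]:ends[i]]), numeric(1)))
}

#' Flag membrane-bound candidates among family isoforms
#'
#' @param proteins named character vector of isoform proteins.
#' @param window,threshold,minLen passed to the profile and span caller.
#' @return data.frame `protein_id`, `start`, `end`, `mean_hydropathy`
#'   (one row per predicted helix; proteins shorter than the window are
#'   skipped).
#' @export
scanTmh <- function(proteins, window = 19L, threshold = 1.6, minLen = 15L) {
  out <- list()
  for (id in names(proteins)) {
    if (nchar(proteins[[id]]) < window) next
    sp <- predictTmh(hydropathyProfile(proteins[[id]], window),
                     threshold, minLen)
    if (nrow(sp)) out[[id]] <- cbind(protein_id = id, sp)
  }
  if (!length(out))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), mean_hydropathy = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Import an externally produced TMH span table
#'
#' Tab-separated `protein_id`, `start`, `end` (header required), as emitted
#' by HMM-based predictors, so real-data runs can use the external tool's
#' calls in place of the hydropathy stand-in.
#'
#' @param path TSV path.
#' @return data.frame with the three columns validated.
#' @export
readTmhTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(tab)))
    stop("TMH table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$end < tab$start)) stop("TMH span with end < start")
  tab
}
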