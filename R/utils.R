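#' @import methods
#' @importFrom stats setNames
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Round half-up to a fixed number of decimals
#'
#' Percentages and ratios in family summary tables are conventionally printed
#' with exact half-up rounding (so 30.225 -> 30.23), which differs from R's
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Kyte-Doolittle hydropathy index
KD_INDEX <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

## strict validation of a protein string; returns normalized (uppercase) form
normalizeProtein <- function(protein, what = "protein") {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein) ||
      nchar(protein) == 0L)
    stop(what, " must be a single non-empty string")
  if (grepl("[a-z]", protein)) {
    warning(what, " contains lowercase residues; normalizing to uppercase")
    protein <- toupper(protein)
  }
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYXBZJUO*.-]", "", protein)
  if (nchar(bad) > 0L)
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  protein
}

## order-stable IRanges sort (avoids S4 sort dispatch)
sortRanges <- function(r) r[order(IRanges::start(r), IRanges::end(r))]

## seeded RNG scope: run code with a local seed without disturbing caller RNG
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
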