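## ---------------------------------------------------------------------------
## conservation: per-position residue diversity and consensus patterns of the
## anchored domain alignment, per cluster / subfamily / genus.
## ---------------------------------------------------------------------------

#' Consensus pattern and per-position diversity of a member group
#'
#' For each alignment column over the given members: the number of distinct
#' non-gap residues and the majority residue (alphabetical first on ties).
#' All-gap columns are shown as `"."` with a count of zero.
#'
#' @param aln [DomainAlignment-class].
#' @param members row names of the group (default: all rows).
#' @param groupId label stored on the result.
#' @return list with `group_id`, `pattern` (string), `n_variants` (integer
#'   vector per column), `motif_region` (`c(start, end)` columns of the
#'   C1--C4 tetrad).
#' @export
groupPattern <- function(aln, members = names(alignedRows(aln)),
                         groupId = "group") {
  if (!length(members)) stop("empty member set")
  m <- alignmentMatrix(aln)
  missing <- setdiff(members, rownames(m))
  if (length(missing))
    stop("members not in alignment: ", paste(missing, collapse = ","))
  m <- m[members, , drop = FALSE]
  nvar <- integer(ncol(m))
  cons <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col != "-" & col != "."]
    if (!length(col)) { nvar[j] <- 0L; cons[j] <- "."; next }
    tab <- table(col)
    nvar[j] <- length(tab)
    cons[j] <- names(tab)[order(-tab, names(tab))][1]
  }
  anch <- anchorColumns(aln)
  list(group_id = groupId, pattern = paste(cons, collapse = ""),
       n_variants = nvar, motif_region = c(anch[1], anch[4]))
}

#' Variable-position summary over pattern rows
#'
#' Pools the motif-region (C1--C4) columns of several group patterns (one
#' per cluster, subfamily, ...): `total` counts every non-gap position of
#' every row, `variable` those whose distinct-residue count exceeds one, and
#' the percentage is half-up rounded to 2 decimals.
#'
#' @param rows list of [groupPattern()] results.
#' @param motifOnly restrict to the motif region (default TRUE); otherwise
#'   the full alignment span is used.
#' @return list `(variable, total, percentage)`.
#' @export
variabilitySummary <- function(rows, motifOnly = TRUE) {
  if (!length(rows)) stop("no pattern rows")
  tot <- 0L; var <- 0L
  for (r in rows) {
    cols <- seq_along(r$n_variants)
    if (motifOnly) cols <- r$motif_region[1]:r$motif_region[2]
    nv <- r$n_variants[cols]
    nv <- nv[nv > 0L]            # gaps excluded
    tot <- tot + length(nv)
    var <- var + sum(nv > 1L)
  }
  if (tot == 0L) stop("no scored positions")
  list(variable = var, total = tot,
       percentage = roundHalfUp(100 * var / tot))
}

#' Compare 100%-conserved positions between two groups
#'
#' For each column, whether group A and group B are each fully conserved
#' (a single non-gap residue), and whether the conserved residues agree.
#' Used e.g. to contrast a genus against an outgroup species, where
#' both-disagreeing columns are subfamily-diagnostic.
#'
#' @param aln [DomainAlignment-class].
#' @param groupA,groupB disjoint, non-empty row-name sets.
#' @return list with per-column data.frame `columns`
#'   (`conserved_a, conserved_b, residue_a, residue_b, status`) and
#'   `summary` counts of
#'   `a_only`, `b_only`, `both_agreeing`, `both_disagreeing`.
#' @export
conservedPositions <- function(aln, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ","))
  m <- alignmentMatrix(aln)
  consOf <- function(col) {
    col <- col[col != "-" & col != "."]
    if (length(col) && length(unique(col)) == 1L) col[1] else NA_character_
  }
  ra <- apply(m[groupA, , drop = FALSE], 2, consOf)
  rb <- apply(m[groupB, , drop = FALSE], 2, consOf)
  status <- ifelse(!is.na(ra) & !is.na(rb),
                   ifelse(ra == rb, "both_agreeing", "both_disagreeing"),
                   ifelse(!is.na(ra), "a_only",
                          ifelse(!is.na(rb), "b_only", "neither")))
  cols <- data.frame(column = seq_len(ncol(m)),
                     conserved_a = !is.na(ra), conserved_b = !is.na(rb),
                     residue_a = ra, residue_b = rb, status = status,
                     stringsAsFactors = FALSE)
  summary <- c(a_only = sum(status == "a_only"),
               b_only = sum(status == "b_only"),
               both_agreeing = sum(status == "both_agreeing"),
               both_disagreeing = sum(status == "both_disagreeing"))
  list(columns = cols, summary = summary)
}

#' Per-position distinct-residue counts for a group
#'
#' Plot-ready diversity curve over the full alignment span (distinct
#' non-gap residues per column).
#'
#' @inheritParams groupPattern
#' @return integer vector, one count per alignment column.
#' @export
positionDiversity <- function(aln, members = names(alignedRows(aln))) {
  groupPattern(aln, members, groupId = "curve")$n_variants
}
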