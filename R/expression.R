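## ---------------------------------------------------------------------------
## expression: FPKM matrix ingestion, hierarchical clustering of genes, and
## per-cluster co-expression coherence labels.
## ---------------------------------------------------------------------------

#' Load a gene x condition FPKM table
#'
#' Delimited text with a header row of condition labels and gene ids in the
#' first column. Missing cells become 0 with a warning (the count is kept in
#' the `n_missing` attribute); duplicate gene ids and negative values are
#' errors.
#'
#' @param path file path (comma- or tab-separated, auto-detected).
#' @param familyIds optional ids to validate against; unknown ids are kept
#'   with a warning.
#' @return numeric matrix (genes x conditions) with attributes `n_missing`
#'   and `transform = "none"`.
#' @export
readFpkm <- function(path, familyIds = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  nmiss <- sum(is.na(m))
  if (nmiss > 0L) {
    warning(nmiss, " missing value(s) set to 0")
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("negative FPKM value(s)")
  if (!is.null(familyIds)) {
    unknown <- setdiff(ids, familyIds)
    if (length(unknown))
      warning("ids not in the family set kept with warning: ",
              paste(unknown, collapse = ","))
  }
  attr(m, "n_missing") <- nmiss
  attr(m, "transform") <- "none"
  m
}

#' Hierarchically cluster expression profiles
#'
#' Applies log2(FPKM + 1) by default, then agglomerates with `hclust`.
#' Distances: euclidean or 1 - Pearson correlation (a zero-variance gene
#' under the correlation distance is an error naming the gene).
#'
#' @param m FPKM matrix (genes x conditions), >= 2 genes.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"complete"` or `"average"`.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return an `hclust` dendrogram over the genes.
#' @export
clusterExpression <- function(m, distance = c("euclidean", "correlation"),
                              linkage = c("complete", "average"),
                              transform = c("log2p1", "none")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  transform <- match.arg(transform)
  if (nrow(m) < 2L) stop("need at least 2 genes")
  x <- if (transform == "log2p1") log2(m + 1) else m
  if (distance == "euclidean") {
    d <- stats::dist(x)
  } else {
    v <- apply(x, 1, stats::sd)
    if (any(v == 0))
      stop("zero-variance gene(s) under correlation distance: ",
           paste(rownames(x)[v == 0], collapse = ","))
    d <- stats::as.dist(1 - stats::cor(t(x)))
  }
  stats::hclust(d, method = linkage)
}

#' Co-expression coherence of gene clusters
#'
#' Cuts the dendrogram into `k` flat clusters and labels each gene cluster
#' (PC): `full` if all its expressed members share one flat cluster,
#' `partial` if at least two members share a flat cluster but not all,
#' `none` otherwise, and `not_assessable` for PCs with fewer than two
#' expressed members.
#'
#' @param dendrogram `hclust` over the expressed genes.
#' @param clusterGenes named list: PC id -> character vector of member gene
#'   ids.
#' @param k flat-cluster count (default: number of PCs with expressed
#'   members).
#' @return named character vector of labels, one per PC.
#' @export
pcCoherence <- function(dendrogram, clusterGenes, k = NULL) {
  genes <- dendrogram$labels
  present <- lapply(clusterGenes, intersect, genes)
  if (is.null(k)) k <- max(1L, sum(lengths(present) >= 1L))
  if (k < 1L || k > length(genes))
    stop("k must be between 1 and the gene count")
  flat <- stats::cutree(dendrogram, k = k)
  vapply(present, function(mem) {
    if (length(mem) < 2L) return("not_assessable")
    f <- flat[mem]
    top <- max(table(f))
    if (top == length(mem)) "full" else if (top >= 2L) "partial" else "none"
  }, character(1))
}
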