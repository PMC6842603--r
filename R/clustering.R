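#' Result of greedy centroid clustering at one identity threshold
#'
#' Clusters partition the input accessions. Every member's identity to its
#' cluster centroid is at least the threshold; centroids have self-identity
#' 1. Clusters with two or more members are "multisequence" (the denominator
#' universe for mislabel rates); single-member clusters are "solitary".
#'
#' @slot threshold Identity threshold in `(0, 1]`.
#' @slot gene Gene id the clustered sequences belong to (may be `""`).
#' @slot members `data.frame` with columns `accession`, `cluster` (integer
#'   id in creation order), `centroid` (accession), `identity`, `length`.
#'
#' @seealso [greedyCluster()]
#' @export
setClass("ClusterSet",
  representation(threshold = "numeric", gene = "character",
                 members = "data.frame"),
  validity = function(object) {
    m <- object@members
    req <- c("accession", "cluster", "centroid", "identity", "length")
    if (!all(req %in% names(m)))
      return(paste("members must have columns", paste(req, collapse = ", ")))
    if (anyDuplicated(m$accession))
      return("accessions must partition into clusters (duplicate found)")
    if (nrow(m) > 0 && any(m$identity < object@threshold - 1e-9))
      return("member identity below the clustering threshold")
    cent <- m$accession %in% m$centroid
    if (nrow(m) > 0 && any(abs(m$identity[m$accession == m$centroid] - 1) > 1e-12))
      return("centroid self-identity must be 1")
    TRUE
  })

#' @describeIn ClusterSet-class number of clusters
#' @param x A `ClusterSet`.
#' @export
setMethod("length", "ClusterSet", function(x) {
  length(unique(x@members$cluster))
})

#' Member table of a ClusterSet
#' @param x A [ClusterSet-class].
#' @return `data.frame` of members (accession, cluster, centroid, identity,
#'   length).
#' @export
clusterMembers <- function(x) x@members

#' Cluster sizes
#' @param x A [ClusterSet-class].
#' @return Named integer vector, cluster id -> size.
#' @export
clusterSizes <- function(x) {
  if (nrow(x@members) == 0) return(integer(0))
  tab <- table(x@members$cluster)
  setNames(as.integer(tab), names(tab))
}

#' Ids of multisequence (nonsolitary) clusters
#' @param x A [ClusterSet-class].
#' @return Integer vector of cluster ids with >= 2 members.
#' @export
multiClusters <- function(x) {
  sz <- clusterSizes(x)
  as.integer(names(sz)[sz >= 2])
}

setMethod("show", "ClusterSet", function(object) {
  sz <- clusterSizes(object)
  cat(sprintf(
    "ClusterSet%s: %d sequences in %d clusters (%d multisequence) at %.2f\n",
    if (nzchar(object@gene)) sprintf(" [%s]", object@gene) else "",
    nrow(object@members), length(sz), sum(sz >= 2), object@threshold))
})

#' Greedy length-sorted centroid clustering
#'
#' Emulates `vsearch --sortbylength --cluster_fast`: records are processed in
#' decreasing length order (ties broken by accession, ascending) and each
#' record joins the first existing centroid, in creation order, whose
#' end-gap-free identity ([pairwiseIdentity()]) reaches the threshold
#' (first-acceptance, not best-match). Otherwise the record founds a new
#' cluster with itself as centroid. The procedure is deterministic; the
#' comparison against centroids is exhaustive (no k-mer prescreen), which
#' bounds the scale this implementation is meant for.
#'
#' @param seqs Named `DNAStringSet` or named character vector (names are
#'   accessions).
#' @param threshold Identity threshold in `(0, 1]`, e.g. 0.97.
#' @param gene Optional gene id stored in the result.
#' @param scheme Nucleotide [ScoringScheme-class] for the identity
#'   alignments.
#' @return A [ClusterSet-class].
#' @examples
#' greedyCluster(c(a = "ACGTACGTAC", b = "ACGTACGTAC"), 0.97)
#' @export
greedyCluster <- function(seqs, threshold, gene = "",
                          scheme = scoringScheme()) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  nm <- names(seqs)
  s <- setNames(as.character(seqs), nm)
  if (length(s) > 0 && (is.null(names(s)) || any(!nzchar(names(s)))))
    stop("sequences must be named by accession")
  empty <- data.frame(accession = character(), cluster = integer(),
                      centroid = character(), identity = numeric(),
                      length = integer(), stringsAsFactors = FALSE)
  if (length(s) == 0)
    return(new("ClusterSet", threshold = threshold, gene = gene,
               members = empty))

  ord <- order(-nchar(s), names(s))
  s <- s[ord]
  enc <- lapply(s, .encodeSeq, scheme = scheme)

  centEnc <- list()
  centAcc <- character()
  cluster <- integer(length(s))
  identity <- numeric(length(s))
  for (i in seq_along(s)) {
    hit <- if (length(centEnc))
      .firstAcceptC(enc[[i]], centEnc, scheme@submat,
                    scheme@gapOpen, scheme@gapExtend, threshold)
    else list(index = 0)
    if (hit$index > 0) {
      cluster[i] <- hit$index
      identity[i] <- hit$identity
    } else {
      centEnc[[length(centEnc) + 1]] <- enc[[i]]
      centAcc[length(centAcc) + 1] <- names(s)[i]
      cluster[i] <- length(centEnc)
      identity[i] <- 1
    }
  }
  new("ClusterSet", threshold = threshold, gene = gene,
      members = data.frame(accession = names(s), cluster = cluster,
                           centroid = centAcc[cluster],
                           identity = identity, length = nchar(s),
                           stringsAsFactors = FALSE))
}

#' Write a ClusterSet as a UC-style table
#'
#' Tab-separated table mirroring the UC layout: record type (`S` seed, `H`
#' hit, `C` cluster summary), cluster id (0-based), size (for `C`) or
#' identity percentage (for `H`), accession, centroid accession.
#'
#' @param x A [ClusterSet-class].
#' @param path Output file path.
#' @return Invisibly, the written `data.frame`.
#' @export
writeClusterTable <- function(x, path) {
  m <- x@members
  sz <- clusterSizes(x)
  rows <- rbind(
    data.frame(type = ifelse(m$accession == m$centroid, "S", "H"),
               cluster = m$cluster - 1L,
               value = ifelse(m$accession == m$centroid, "*",
                              sprintf("%.1f", 100 * m$identity)),
               accession = m$accession, centroid = m$centroid,
               stringsAsFactors = FALSE),
    data.frame(type = "C", cluster = as.integer(names(sz)) - 1L,
               value = as.character(sz),
               accession = m$centroid[match(as.integer(names(sz)),
                                            m$cluster)],
               centroid = "*", stringsAsFactors = FALSE))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(rows)
}
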