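# Taxonomic-incongruence detection and min/max mislabel bounding.
#
# A cluster is discordant at a rank when its members carry >= 2 distinct
# named taxa there. Assuming at least one annotation is correct, the number
# of mislabeled members is bracketed by
#   min = n - (largest taxon count)   (the plurality taxon is correct)
#   max = n - (smallest taxon count)  (only the rarest taxon is correct)
# over members with a named taxon at that rank. Members that are "unranked"
# at the audited rank are excluded from its counts rather than treated as a
# taxon of their own, which would fabricate discordance.

#' Taxon composition and discordant ranks of a cluster
#'
#' Counts the distinct named taxa among a cluster's members at each audited
#' rank (members `"unranked"` at a rank are excluded there) and reports the
#' ranks with two or more distinct taxa. Discordance is hierarchical: a
#' cluster discordant at some rank is discordant at every rank below it.
#'
#' @param accessions Member accessions.
#' @param lineages `data.frame` as returned by [lineageTable()], with
#'   row-per-accession lineage columns and an `accession` column, or row
#'   names equal to accessions.
#' @return A list of class `"discordance_report"`: `counts` (named list,
#'   rank -> named integer vector of taxon counts), `discordant` (character
#'   vector of discordant ranks), `n` (cluster size).
#' @export
flagDiscordant <- function(accessions, lineages) {
  lin <- .lineageRows(lineages, accessions)
  counts <- lapply(AUDIT_RANKS, function(r) {
    v <- lin[[r]]
    v <- v[!is.na(v) & v != "unranked"]
    if (length(v) == 0) return(integer(0))
    tab <- table(v)
    setNames(as.integer(tab), names(tab))
  })
  names(counts) <- AUDIT_RANKS
  discordant <- AUDIT_RANKS[vapply(counts, length, 0L) >= 2]
  structure(list(counts = counts, discordant = discordant,
                 n = length(accessions)),
            class = "discordance_report")
}

.lineageRows <- function(lineages, accessions) {
  if ("accession" %in% names(lineages)) {
    i <- match(accessions, lineages$accession)
  } else {
    i <- match(accessions, rownames(lineages))
  }
  if (anyNA(i))
    stop(sprintf("missing lineage for accession(s): %s",
                 paste(accessions[is.na(i)], collapse = ", ")))
  lineages[i, , drop = FALSE]
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("cluster of %d: discordant at {%s}\n", x$n,
              paste(x$discordant, collapse = ", ")))
  invisible(x)
}

#' Minimum and maximum mislabel counts for one rank
#'
#' Given the taxon counts of a cluster at a rank, returns the min/max
#' bracket on the number of mislabeled members: `min` assumes the largest
#' taxon is the correct one, `max` assumes the smallest is. A concordant
#' rank (one taxon or none) yields `min = max = 0`. Ties for the largest or
#' smallest taxon are immaterial because only the count enters the bound.
#'
#' @param report A `"discordance_report"` from [flagDiscordant()], or a
#'   named integer vector of taxon counts.
#' @param rank One of [AUDIT_RANKS] (ignored when counts are given
#'   directly).
#' @return A list: `rank`, `n` (members considered, i.e. named at the
#'   rank), `min`, `max`.
#' @examples
#' minMaxMislabels(c(A = 3, B = 2, C = 1))  # min 3, max 5
#' @export
minMaxMislabels <- function(report, rank = NULL) {
  counts <- if (inherits(report, "discordance_report")) {
    if (is.null(rank) || !rank %in% AUDIT_RANKS)
      stop("rank must be one of the audited ranks")
    report$counts[[rank]]
  } else {
    report
  }
  n <- sum(counts)
  if (length(counts) <= 1)
    return(list(rank = rank, n = n, min = 0L, max = 0L))
  list(rank = rank, n = n,
       min = as.integer(n - max(counts)),
       max = as.integer(n - min(counts)))
}

#' Resolve individual mislabeled members by similarity consensus
#'
#' A deterministic stand-in for the manual phylogenetic (distance-tree)
#' inspection of flagged clusters. For every member the mean pairwise
#' identity to each taxon group at the audited rank (excluding the member
#' itself) is computed and compared:
#' members of the plurality label are `"correct"`; a member whose label is
#' not the plurality is `"mislabeled"` when its own-label group offers no
#' support (it is the group's only member) or when some other group's mean
#' identity exceeds its own-label group's by more than `epsilon`, and
#' `"correct"` when its own group beats every other by more than `epsilon`.
#' When the similarity evidence is uninformative (all group means within
#' `epsilon`), a clear plurality consensus decides: the member is
#' `"mislabeled"` if the plurality group has at least twice the members of
#' its own group, else `"unresolved"`. Every member of a cluster whose
#' plurality is tied is `"unresolved"`.
#'
#' @param accessions Member accessions of a cluster discordant at `rank`.
#' @param lineages Lineage table (see [flagDiscordant()]).
#' @param rank Audited rank at which to resolve.
#' @param idmat Symmetric pairwise identity matrix over the members (see
#'   [identityMatrix()]).
#' @param epsilon Mean-identity margin below which groups are considered
#'   inseparable (default 0.005).
#' @return Named character vector over `accessions` with values
#'   `"correct"`, `"mislabeled"` or `"unresolved"`; members unranked at
#'   `rank` are `NA`.
#' @export
resolveMislabels <- function(accessions, lineages, rank, idmat,
                             epsilon = 0.005) {
  lin <- .lineageRows(lineages, accessions)
  lab <- lin[[rank]]
  named <- !is.na(lab) & lab != "unranked"
  if (length(unique(lab[named])) < 2)
    stop(sprintf("cluster is not discordant at rank '%s'", rank))
  out <- setNames(rep(NA_character_, length(accessions)), accessions)
  tab <- table(lab[named])
  plurality <- if (sum(tab == max(tab)) == 1) names(tab)[which.max(tab)]
               else NA_character_
  groups <- split(accessions[named], lab[named])
  for (k in which(named)) {
    acc <- accessions[k]
    own <- lab[k]
    if (!is.na(plurality) && own == plurality) {
      out[acc] <- "correct"
      next
    }
    if (is.na(plurality)) {
      out[acc] <- "unresolved"
      next
    }
    means <- vapply(groups, function(g) {
      g <- setdiff(g, acc)
      if (length(g) == 0) return(NA_real_)
      mean(idmat[acc, g])
    }, 0)
    ownMean <- means[[own]]
    others <- means[setdiff(names(means), own)]
    others <- others[!is.na(others)]
    if (length(others) == 0) {
      out[acc] <- "unresolved"
    } else if (is.na(ownMean)) {
      out[acc] <- "mislabeled"
    } else if (max(others) - ownMean > epsilon) {
      out[acc] <- "mislabeled"
    } else if (ownMean - max(others) > epsilon) {
      out[acc] <- "correct"
    } else if (tab[[plurality]] >= 2 * tab[[own]]) {
      # similarity uninformative: defer to a clear plurality consensus
      out[acc] <- "mislabeled"
    } else {
      out[acc] <- "unresolved"
    }
  }
  out
}

#' Aggregate per-cluster mislabel bounds into per-rank estimates
#'
#' Walks every multisequence cluster of a [ClusterSet-class], computes the
#' min/max mislabel bracket per audited rank, optionally replaces the
#' bracket by an exact resolved count for large clusters (size >=
#' `largeMin`) that the similarity-consensus resolver settles completely,
#' and sums across clusters. Counts are cumulative down ranks: the per-rank
#' computation counts every member whose label conflicts at that rank *or
#' above* (a genus-level count therefore includes family-level errors, as
#' in a table reading "at or above the level of"). An exclusive per-rank
#' view is available with `cumulative = FALSE`. Rates are percentages of
#' the total number of sequences in multisequence clusters.
#'
#' @param clusterset A [ClusterSet-class].
#' @param lineages Lineage table covering all member accessions (an
#'   `accession` column or row names).
#' @param seqs Named sequences (needed only when `resolveLarge = TRUE`, to
#'   compute within-cluster identity matrices).
#' @param largeMin Minimum cluster size for exact resolution (default 100,
#'   the large-cluster strategy; clusters below it keep their bounds).
#' @param resolveLarge Resolve large discordant clusters member-by-member;
#'   clusters with any unresolved member fall back to their bounds.
#' @param epsilon Margin for [resolveMislabels()].
#' @param cumulative Report cumulative ("at or above rank") counts
#'   (default) or exclusive per-rank counts.
#' @param scheme Nucleotide scoring scheme for identity matrices.
#' @return `data.frame` with one row per rank: `rank`, `minCount`,
#'   `maxCount`, `minRate`, `maxRate` (percent), `denominator`. The
#'   per-cluster detail is attached as `attr(, "details")` (columns
#'   `cluster`, `rank`, `taxa`, `min`, `max`, `status`).
#' @export
aggregateMislabels <- function(clusterset, lineages, seqs = NULL,
                               largeMin = 100, resolveLarge = TRUE,
                               epsilon = 0.005, cumulative = TRUE,
                               scheme = scoringScheme()) {
  m <- clusterMembers(clusterset)
  sz <- clusterSizes(clusterset)
  multi <- as.integer(names(sz)[sz >= 2])
  denom <- sum(sz[sz >= 2])
  minC <- setNames(rep(0L, length(AUDIT_RANKS)), AUDIT_RANKS)
  maxC <- minC
  details <- list()
  for (cid in multi) {
    accs <- m$accession[m$cluster == cid]
    rep_ <- flagDiscordant(accs, lineages)
    if (length(rep_$discordant) == 0) next
    idmat <- NULL
    for (r in rep_$discordant) {
      b <- minMaxMislabels(rep_, r)
      status <- "bounds"
      if (resolveLarge && length(accs) >= largeMin && !is.null(seqs)) {
        if (is.null(idmat))
          idmat <- identityMatrix(seqs[accs], scheme = scheme)
        res <- resolveMislabels(accs, lineages, r, idmat, epsilon)
        res <- res[!is.na(res)]
        if (!any(res == "unresolved")) {
          b$min <- b$max <- sum(res == "mislabeled")
          status <- "resolved"
        }
      }
      minC[r] <- minC[r] + b$min
      maxC[r] <- maxC[r] + b$max
      details[[length(details) + 1]] <- data.frame(
        cluster = cid, rank = r,
        taxa = paste(sprintf("%s=%d", names(rep_$counts[[r]]),
                             rep_$counts[[r]]), collapse = ";"),
        min = b$min, max = b$max, status = status,
        stringsAsFactors = FALSE)
    }
  }
  if (!cumulative) {
    # difference successive ranks; clamp at zero against resolution jitter
    minC <- pmax(minC - c(0L, head(minC, -1)), 0L)
    maxC <- pmax(maxC - c(0L, head(maxC, -1)), 0L)
  }
  out <- data.frame(
    rank = AUDIT_RANKS, minCount = as.integer(minC),
    maxCount = as.integer(maxC),
    minRate = if (denom > 0) 100 * minC / denom else 0,
    maxRate = if (denom > 0) 100 * maxC / denom else 0,
    denominator = denom, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "details") <- if (length(details)) do.call(rbind, details)
    else data.frame(cluster = integer(), rank = character(),
                    taxa = character(), min = integer(), max = integer(),
                    status = character(), stringsAsFactors = FALSE)
  out
}
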