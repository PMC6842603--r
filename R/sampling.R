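# Simulation of estimation strategies for the database error rate, on a
# clustered database with known truth. Auditing a cluster reveals the exact
# number of mislabeled sequences it contains; strategies differ in which
# clusters get audited for a given effort (number of clusters checked).

#' Simulate an error-rate estimation strategy
#'
#' Strategies:
#' * `random-sequence`: draw sequences uniformly and audit each drawn
#'   sequence's containing cluster (deduplicated) until `effort` distinct
#'   clusters have been audited. Large clusters are sampled preferentially
#'   (size-biased), which biases the estimate when error rate covaries with
#'   cluster size.
#' * `random-cluster`: draw `effort` clusters uniformly without
#'   replacement; the reported rate is the expansion estimator
#'   `100 * (N/effort) * mislabeled / totalSequences`, which is exactly
#'   unbiased for the database rate.
#' * `large-cluster-exhaustive`: audit every cluster of size >=
#'   `largeMin` exactly and bracket the remainder with the min/max bounds
#'   from its label counts; the reported estimate is the bracket midpoint.
#'
#' For random-sequence sampling the estimate is the ratio estimator
#' `100 * mislabeled / sequences` over the audited clusters. All
#' randomness derives from `seed`; per-replicate seeds are `seed + 1 ...
#' seed + replicates`.
#'
#' @param truth `data.frame` with one row per sequence: columns
#'   `accession`, `cluster` (cluster id), `label` (taxon label at the
#'   audited rank, used for the bounds of the exhaustive strategy) and
#'   `isMislabeled` (logical truth).
#' @param strategy One of `"random-sequence"`, `"random-cluster"`,
#'   `"large-cluster-exhaustive"`.
#' @param effort Number of clusters to audit (capped, with a warning, at
#'   the number of clusters).
#' @param replicates Number of independent replicates.
#' @param seed Integer seed.
#' @param largeMin Size cutoff for the exhaustive strategy.
#' @return `data.frame` with one row per replicate: `strategy`,
#'   `replicate`, `seed`, `effort` (clusters audited), `estimate`,
#'   `estMin`, `estMax` (percent; equal to `estimate` for the sampling
#'   strategies), `truthRate` (planted percent).
#' @export
simulateStrategy <- function(truth,
                             strategy = c("random-sequence",
                                          "random-cluster",
                                          "large-cluster-exhaustive"),
                             effort, replicates = 1, seed,
                             largeMin = 100) {
  strategy <- match.arg(strategy)
  if (effort < 1) stop("effort must be at least 1")
  if (missing(seed)) stop("a seed is required")
  req <- c("accession", "cluster", "label", "isMislabeled")
  if (!all(req %in% names(truth)))
    stop(paste("truth must have columns", paste(req, collapse = ", ")))

  clusters <- unique(truth$cluster)
  nc <- length(clusters)
  if (effort > nc && strategy != "large-cluster-exhaustive") {
    warning(sprintf("effort %d exceeds the %d available clusters; capped",
                    effort, nc))
    effort <- nc
  }
  truthRate <- 100 * mean(truth$isMislabeled)
  clMis <- tapply(truth$isMislabeled, truth$cluster, sum)
  clSize <- tapply(truth$isMislabeled, truth$cluster, length)

  rows <- lapply(seq_len(replicates), function(rep_) {
    rseed <- seed + rep_
    .withSeed(rseed, {
      if (strategy == "random-sequence") {
        picked <- character(0)
        ord <- sample(truth$cluster)  # uniform sequence draws, dedup
        for (cl in ord) {
          if (!cl %in% picked) picked <- c(picked, cl)
          if (length(picked) >= effort) break
        }
        audited <- picked
      } else if (strategy == "random-cluster") {
        audited <- sample(as.character(clusters), effort)
      } else {
        audited <- as.character(clusters[clSize[as.character(clusters)] >=
                                           largeMin])
      }
      if (strategy == "large-cluster-exhaustive") {
        rest <- setdiff(as.character(clusters), audited)
        bmin <- 0; bmax <- 0
        for (cl in rest) {
          b <- minMaxMislabels(table(truth$label[truth$cluster == cl]))
          bmin <- bmin + b$min; bmax <- bmax + b$max
        }
        misA <- sum(clMis[audited])
        total <- nrow(truth)
        estMin <- 100 * (misA + bmin) / total
        estMax <- 100 * (misA + bmax) / total
        est <- (estMin + estMax) / 2
        nAudited <- length(audited)
      } else if (strategy == "random-sequence") {
        # ratio estimator over the audited clusters (size-biased inclusion)
        mis <- sum(clMis[audited])
        nseq <- sum(clSize[audited])
        est <- estMin <- estMax <- 100 * mis / nseq
        nAudited <- length(audited)
      } else {
        # expansion estimator: unbiased for the database rate under
        # uniform cluster sampling
        mis <- sum(clMis[audited])
        est <- estMin <- estMax <-
          100 * (nc / length(audited)) * mis / nrow(truth)
        nAudited <- length(audited)
      }
      data.frame(strategy = strategy, replicate = rep_, seed = rseed,
                 effort = nAudited, estimate = est, estMin = estMin,
                 estMax = estMax, truthRate = truthRate,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Compare estimation strategies
#'
#' Per-strategy mean bias (estimate minus truth), its Monte-Carlo standard
#' error, RMSE, and for bracketing strategies the coverage of the
#' `[estMin, estMax]` interval.
#'
#' @param results Row-bound output of [simulateStrategy()] for two or more
#'   strategies.
#' @return `data.frame` with one row per strategy: `strategy`,
#'   `replicates`, `meanBias`, `seBias`, `rmse`, `coverage`.
#' @export
compareStrategies <- function(results) {
  if (length(unique(results$strategy)) < 2)
    stop("need results from at least two strategies")
  rows <- lapply(split(results, results$strategy), function(d) {
    err <- d$estimate - d$truthRate
    data.frame(
      strategy = d$strategy[1], replicates = nrow(d),
      meanBias = mean(err),
      seBias = if (nrow(d) > 1) sd(err) / sqrt(nrow(d)) else NA_real_,
      rmse = sqrt(mean(err^2)),
      coverage = mean(d$estMin - 1e-9 <= d$truthRate &
                        d$truthRate <= d$estMax + 1e-9),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truth table for sampling simulations from a clustered AuditDb
#'
#' Joins a [ClusterSet-class] with a synthetic database's truth table into
#' the per-sequence format [simulateStrategy()] expects, restricted to
#' clustered sequences.
#'
#' @param db A synthetic [AuditDb-class].
#' @param clusterset A [ClusterSet-class] over (a subset of) its records.
#' @return `data.frame` with columns `accession`, `cluster`, `label`,
#'   `isMislabeled`.
#' @export
samplingTruth <- function(db, clusterset) {
  m <- clusterMembers(clusterset)
  tr <- dbTruth(db)
  i <- match(m$accession, tr$accession)
  data.frame(accession = m$accession, cluster = m$cluster,
             label = tr$lab_genus[i], isMislabeled = tr$isMislabeled[i],
             stringsAsFactors = FALSE)
}
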