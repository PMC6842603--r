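# End-to-end orchestration: simulate (optional) -> classify -> length
# filter -> cluster per threshold -> flag -> bound -> resolve -> causes ->
# aggregate -> report bundle.

#' Pipeline configuration
#'
#' @param simSpec A [simSpec()] for simulate mode, or `NULL` when `db` is
#'   supplied to [runPipeline()].
#' @param thresholds Clustering identity thresholds (default
#'   `c(0.97, 0.98, 0.99, 1.00)`).
#' @param headline Threshold whose estimates head the report (default
#'   0.97, the most inclusive of the data); must be in `thresholds`.
#' @param largeMin Minimum cluster size for exact member-level resolution
#'   (default 100).
#' @param classify Run gene classification and the length filter (default
#'   `TRUE`); when `FALSE` the declared gene in the metadata is trusted.
#' @param causeConfig A [causeConfig()].
#' @param epsilon Margin for the similarity-consensus resolver.
#' @param outDir Optional output directory for the report bundle.
#' @param seed Integer seed (mandatory in simulate mode).
#' @return A list of class `"pipeline_config"`.
#' @export
pipelineConfig <- function(simSpec = NULL,
                           thresholds = c(0.97, 0.98, 0.99, 1.00),
                           headline = 0.97, largeMin = 100,
                           classify = TRUE, causeConfig = NULL,
                           epsilon = 0.005, outDir = NULL, seed = NULL) {
  if (!headline %in% thresholds)
    stop("headline threshold must be one of the thresholds")
  structure(list(simSpec = simSpec, thresholds = thresholds,
                 headline = headline, largeMin = largeMin,
                 classify = classify, causeConfig = causeConfig,
                 epsilon = epsilon, outDir = outDir, seed = seed),
            class = "pipeline_config")
}

#' Run the audit pipeline end to end
#'
#' Executes every stage on a supplied or simulated database and returns a
#' report bundle: per-threshold rank estimates, per-cluster details, the
#' cause table for resolved mislabels at the headline threshold, and a
#' deterministic JSON-ready summary. Identical configuration and seed give
#' an identical bundle. Each stage logs its in/out counts via `message()`,
#' and the classification stage asserts count conservation
#' (in = assigned + multi-gene + below-threshold + length-filtered).
#'
#' @param config A [pipelineConfig()].
#' @param db An [AuditDb-class]; when `NULL`, `config$simSpec` is
#'   simulated with `config$seed`.
#' @return A list of class `"audit_report"`: `db`, `assignments`,
#'   `clusters` (list, one [ClusterSet-class] per threshold per gene),
#'   `estimates` (list of `data.frame`s keyed by threshold), `causes`,
#'   `summary` (plain list). When `config$outDir` is set, TSV tables and
#'   `summary.json` are written there.
#' @export
runPipeline <- function(config = pipelineConfig(), db = NULL) {
  t0 <- Sys.time()
  if (is.null(db)) {
    if (is.null(config$simSpec))
      stop("either a database or a simSpec must be provided")
    if (is.null(config$seed))
      stop("a seed is mandatory in simulate mode")
    message("stage simulate: generating synthetic database")
    db <- simulateDatabase(config$simSpec, seed = config$seed)
  }
  meta <- dbMeta(db)
  seqs <- dbSeqs(db)
  message(sprintf("stage input: %d records", length(seqs)))

  ## ---- classification + length filter ----
  if (config$classify) {
    if (length(dbRefs(db)) == 0)
      stop("stage classify failed: no reference panels in database")
    assignments <- classifyGenes(seqs, dbRefs(db))
    nIn <- nrow(assignments)
    nMulti <- sum(assignments$discardedReason %in% "multi-gene")
    nBelow <- sum(assignments$discardedReason %in% "below-threshold")
    nLen <- sum(assignments$discardedReason %in% "length-out-of-range")
    nKept <- sum(assignments$gene != "unassigned" &
                   is.na(assignments$discardedReason))
    stopifnot(nIn == nKept + nMulti + nBelow + nLen)
    message(sprintf(
      "stage classify: %d in = %d assigned + %d multi-gene + %d below-threshold + %d length-filtered",
      nIn, nKept, nMulti, nBelow, nLen))
    keep <- assignments$accession[assignments$gene != "unassigned" &
                                    is.na(assignments$discardedReason)]
    geneOf <- setNames(assignments$gene, assignments$accession)
  } else {
    assignments <- data.frame(accession = meta$accession,
                              gene = meta$gene, stringsAsFactors = FALSE)
    keep <- meta$accession
    geneOf <- setNames(meta$gene, meta$accession)
    message("stage classify: skipped (declared genes trusted)")
  }

  lineages <- dbLineages(db)

  ## ---- clustering, flagging, bounding per gene x threshold ----
  scheme <- scoringScheme()
  clusters <- list()
  estimates <- list()
  genes <- unique(geneOf[keep])
  for (th in config$thresholds) {
    thKey <- sprintf("%.2f", th)
    perGene <- list()
    combined <- NULL
    for (g in genes) {
      accs <- keep[geneOf[keep] == g]
      cs <- greedyCluster(seqs[accs], th, gene = g, scheme = scheme)
      perGene[[g]] <- cs
      est <- aggregateMislabels(cs, lineages, seqs = seqs,
                                largeMin = config$largeMin,
                                epsilon = config$epsilon, scheme = scheme)
      est$gene <- g
      combined <- if (is.null(combined)) est else .combineEstimates(combined, est)
    }
    clusters[[thKey]] <- perGene
    estimates[[thKey]] <- combined
    message(sprintf(
      "stage cluster %.2f: %s", th,
      paste(vapply(genes, function(g)
        sprintf("%s: %d clusters (%d multi)", g, length(perGene[[g]]),
                length(multiClusters(perGene[[g]]))), ""),
        collapse = "; ")))
  }

  ## ---- causes at the headline threshold ----
  headKey <- sprintf("%.2f", config$headline)
  cconf <- config$causeConfig
  if (is.null(cconf))
    cconf <- causeConfig(bacterialPanel = dbBacterial(db),
                         synonyms = dbSynonyms(db))
  defs <- setNames(meta$definition, meta$accession)
  causes <- .auditCauses(clusters[[headKey]], lineages, seqs, defs, cconf,
                         config$epsilon, scheme)
  message(sprintf("stage causes: %d resolved mislabels classified",
                  nrow(causes)))

  ## ---- summary ----
  head_ <- estimates[[headKey]]
  summary <- list(
    nRecords = length(seqs),
    genes = as.list(setNames(vapply(genes, function(g)
      sum(geneOf[keep] == g), 0L), genes)),
    thresholds = config$thresholds,
    headlineThreshold = config$headline,
    headline = lapply(seq_len(nrow(head_)), function(i) list(
      rank = head_$rank[i], minCount = head_$minCount[i],
      maxCount = head_$maxCount[i],
      minRate = round(head_$minRate[i], 4),
      maxRate = round(head_$maxRate[i], 4),
      denominator = head_$denominator[i])),
    causes = if (nrow(causes)) as.list(table(causes$cause)) else list(),
    seed = config$seed)

  report <- list(db = db, assignments = assignments, clusters = clusters,
                 estimates = estimates, causes = causes, summary = summary)
  class(report) <- "audit_report"

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(assignments, file.path(config$outDir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (th in names(clusters))
      for (g in names(clusters[[th]]))
        writeClusterTable(clusters[[th]][[g]], file.path(
          config$outDir, sprintf("clusters_%s_%s.tsv", g, th)))
    for (th in names(estimates)) {
      write.table(estimates[[th]],
                  file.path(config$outDir, sprintf("estimates_%s.tsv", th)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      det <- attr(estimates[[th]], "details")
      if (!is.null(det))
        write.table(det, file.path(config$outDir,
                                   sprintf("cluster_detail_%s.tsv", th)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(causes, file.path(config$outDir, "causes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  report
}

# sum two per-gene estimate tables into combined counts/rates
.combineEstimates <- function(a, b) {
  out <- a
  out$minCount <- a$minCount + b$minCount
  out$maxCount <- a$maxCount + b$maxCount
  out$denominator <- a$denominator + b$denominator
  out$minRate <- ifelse(out$denominator > 0,
                        100 * out$minCount / out$denominator, 0)
  out$maxRate <- ifelse(out$denominator > 0,
                        100 * out$maxCount / out$denominator, 0)
  out$gene <- "combined"
  attr(out, "details") <- rbind(attr(a, "details"), attr(b, "details"))
  out
}

# resolve every discordant multisequence cluster at genus rank and classify
# the cause of each member called mislabeled
.auditCauses <- function(perGene, lineages, seqs, definitions, cconf,
                         epsilon, scheme) {
  rows <- list()
  for (g in names(perGene)) {
    cs <- perGene[[g]]
    m <- clusterMembers(cs)
    for (cid in multiClusters(cs)) {
      accs <- m$accession[m$cluster == cid]
      rep_ <- flagDiscordant(accs, lineages)
      if (!"genus" %in% rep_$discordant) next
      idmat <- identityMatrix(seqs[accs], scheme = scheme)
      res <- resolveMislabels(accs, lineages, "genus", idmat, epsilon)
      flagged <- names(res)[!is.na(res) & res == "mislabeled"]
      for (acc in flagged)
        rows[[length(rows) + 1]] <- classifyCause(
          acc, accs, lineages, seqs, definitions, cconf, idmat = idmat,
          scheme = scheme)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(accession = character(), cause = character(),
                  evidence = character(), stringsAsFactors = FALSE)
}
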