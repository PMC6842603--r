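#' An auditable sequence database
#'
#' Container for one database under audit: the nucleotide records, their
#' per-record metadata (accession, labeled taxon id, gene, definition), the
#' taxonomy the labels refer to, per-gene reference panels, an optional
#' machine-readable truth table (synthetic databases), a genus synonym
#' table and an optional bacterial reference panel.
#'
#' @slot seqs Named `DNAStringSet` (names are accessions).
#' @slot meta `data.frame` with columns `accession`, `taxid`, `gene`,
#'   `definition`.
#' @slot taxonomy A [TaxonomyTable-class].
#' @slot refs Named list of per-gene reference panels (`AAStringSet` for
#'   protein-coding genes, `DNAStringSet` for ribosomal genes).
#' @slot truth `data.frame` truth table (zero rows for real data): per
#'   record the true and labeled lineages, mislabel flag, planted cause and
#'   planted rank.
#' @slot synonyms `data.frame` with columns `old`, `current` (genus
#'   synonyms).
#' @slot bacterial `DNAStringSet` bacterial reference panel (may be empty).
#' @slot simSpec Resolved generator settings (empty list for real data).
#'
#' @include taxonomy.R
#' @importClassesFrom Biostrings DNAStringSet
#' @export
setClass("AuditDb",
  representation(seqs = "DNAStringSet", meta = "data.frame",
                 taxonomy = "TaxonomyTable", refs = "list",
                 truth = "data.frame", synonyms = "data.frame",
                 bacterial = "DNAStringSet", simSpec = "list"),
  validity = function(object) {
    if (!identical(names(object@seqs), object@meta$accession))
      return("seqs and meta must be aligned by accession")
    if (nrow(object@truth) > 0 &&
        !identical(object@truth$accession, object@meta$accession))
      return("truth table must be aligned with meta by accession")
    bad <- setdiff(object@meta$taxid, object@taxonomy@nodes$taxid)
    if (length(bad))
      return(sprintf("labeled taxid(s) missing from taxonomy: %s",
                     paste(head(bad, 5), collapse = ", ")))
    TRUE
  })

#' @describeIn AuditDb-class number of records
#' @param x An `AuditDb`.
#' @export
setMethod("length", "AuditDb", function(x) length(x@seqs))

#' Accessors for AuditDb slots
#' @param x An [AuditDb-class].
#' @return The corresponding slot.
#' @name AuditDb-accessors
NULL

#' @rdname AuditDb-accessors
#' @export
dbSeqs <- function(x) x@seqs
#' @rdname AuditDb-accessors
#' @export
dbMeta <- function(x) x@meta
#' @rdname AuditDb-accessors
#' @export
dbTaxonomy <- function(x) x@taxonomy
#' @rdname AuditDb-accessors
#' @export
dbRefs <- function(x) x@refs
#' @rdname AuditDb-accessors
#' @export
dbTruth <- function(x) x@truth
#' @rdname AuditDb-accessors
#' @export
dbSynonyms <- function(x) x@synonyms
#' @rdname AuditDb-accessors
#' @export
dbBacterial <- function(x) x@bacterial

setMethod("show", "AuditDb", function(object) {
  cat(sprintf("AuditDb: %d records, %d taxa, genes: %s\n",
              length(object@seqs), nrow(object@taxonomy@nodes),
              paste(unique(object@meta$gene), collapse = ", ")))
  if (nrow(object@truth) > 0)
    cat(sprintf("  synthetic; %d planted mislabels\n",
                sum(object@truth$isMislabeled)))
})

#' Labeled lineages for every record of a database
#'
#' Convenience wrapper: [lineageTable()] over the records' labeled taxon
#' ids, keyed by accession.
#'
#' @param db An [AuditDb-class].
#' @return `data.frame` with columns `accession`, `taxid`, and the five
#'   audited ranks.
#' @export
dbLineages <- function(db) {
  lt <- lineageTable(db@taxonomy, db@meta$taxid)
  cbind(accession = db@meta$accession, lt, stringsAsFactors = FALSE)
}

#' Write an AuditDb to a directory of plain-text files
#'
#' Emits `<gene>.fasta` (headers `accession|taxid`, wrapped at 80 columns),
#' `nodes.dmp` / `names.dmp` in taxdump dialect, `truth.tsv` (when
#' present), `synonyms.tsv`, per-gene reference panels (`<gene>.faa` for
#' amino acid, `<gene>.fna` for nucleotide), `bacterial.fna` (when
#' present), and `spec.json` with the resolved generator settings.
#'
#' @param db An [AuditDb-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeAuditDb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in unique(db@meta$gene)) {
    keep <- db@meta$gene == g
    s <- db@seqs[keep]
    names(s) <- sprintf("%s|%d", db@meta$accession[keep],
                        db@meta$taxid[keep])
    Biostrings::writeXStringSet(s, file.path(dir, sprintf("%s.fasta", g)),
                                width = 80)
  }
  nd <- db@taxonomy@nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nd$taxid, nd$parent, nd$rank),
             file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     nd$taxid, nd$name),
             file.path(dir, "names.dmp"))
  if (nrow(db@truth) > 0)
    write.table(db@truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(db@synonyms, file.path(dir, "synonyms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in names(db@refs)) {
    ext <- if (is(db@refs[[g]], "AAStringSet")) "faa" else "fna"
    Biostrings::writeXStringSet(db@refs[[g]],
                                file.path(dir, sprintf("%s.%s", g, ext)),
                                width = 80)
  }
  if (length(db@bacterial))
    Biostrings::writeXStringSet(db@bacterial,
                                file.path(dir, "bacterial.fna"), width = 80)
  jsonlite::write_json(db@simSpec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an AuditDb back from a directory
#'
#' Counterpart of [writeAuditDb()]; parses the per-gene FASTA files
#' (headers `accession|taxid`), the taxdump files and, when present, the
#' truth table, synonyms, reference panels and bacterial panel.
#'
#' @param dir Directory written by [writeAuditDb()] (or hand-assembled in
#'   the same layout).
#' @return An [AuditDb-class].
#' @export
readAuditDb <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  fastas <- fastas[basename(fastas) != "bacterial.fasta"]
  if (length(fastas) == 0) stop("no <gene>.fasta files found")
  seqs <- NULL
  meta <- list()
  for (f in fastas) {
    g <- sub("\\.fasta$", "", basename(f))
    s <- Biostrings::readDNAStringSet(f)
    parts <- strsplit(names(s), "|", fixed = TRUE)
    acc <- vapply(parts, `[`, "", 1L)
    taxid <- as.integer(vapply(parts, `[`, "", 2L))
    names(s) <- acc
    seqs <- if (is.null(seqs)) s else c(seqs, s)
    meta[[length(meta) + 1]] <- data.frame(
      accession = acc, taxid = taxid, gene = g,
      definition = NA_character_, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  tax <- loadTaxdump(file.path(dir, "nodes.dmp"),
                     file.path(dir, "names.dmp"))
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath))
    read.table(truthPath, sep = "\t", header = TRUE, quote = "",
               comment.char = "", stringsAsFactors = FALSE)
  else data.frame()
  if (nrow(truth) > 0) {
    i <- match(meta$accession, truth$accession)
    truth <- truth[i, , drop = FALSE]
    rownames(truth) <- NULL
    meta$definition <- truth$definition
  }
  synPath <- file.path(dir, "synonyms.tsv")
  syn <- if (file.exists(synPath))
    read.table(synPath, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               colClasses = "character")
  else data.frame(old = character(), current = character(),
                  stringsAsFactors = FALSE)
  refs <- list()
  for (f in list.files(dir, pattern = "\\.faa$", full.names = TRUE))
    refs[[sub("\\.faa$", "", basename(f))]] <- Biostrings::readAAStringSet(f)
  for (f in list.files(dir, pattern = "\\.fna$", full.names = TRUE)) {
    g <- sub("\\.fna$", "", basename(f))
    if (g != "bacterial") refs[[g]] <- Biostrings::readDNAStringSet(f)
  }
  bact <- if (file.exists(file.path(dir, "bacterial.fna")))
    Biostrings::readDNAStringSet(file.path(dir, "bacterial.fna"))
  else Biostrings::DNAStringSet()
  specPath <- file.path(dir, "spec.json")
  spec <- if (file.exists(specPath))
    jsonlite::read_json(specPath, simplifyVector = TRUE) else list()
  new("AuditDb", seqs = seqs, meta = meta, taxonomy = tax, refs = refs,
      truth = truth, synonyms = syn, bacterial = bact,
      simSpec = as.list(spec))
}
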