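#' Ranked taxonomy table
#'
#' A parsed taxdump-style taxonomy: one row per taxon with its parent, rank
#' and scientific name. Exactly one root (a node that is its own parent) is
#' required and every parent chain must terminate there without cycles.
#' Ranks outside `phylum/class/order/family/genus/species` are carried as
#' `"no-rank"`.
#'
#' @slot nodes `data.frame` with columns `taxid` (integer), `parent`
#'   (integer), `rank` (character), `name` (character).
#'
#' @seealso [loadTaxdump()], [lineageOf()]
#' @export
setClass("TaxonomyTable", representation(nodes = "data.frame"),
  validity = function(object) {
    nd <- object@nodes
    req <- c("taxid", "parent", "rank", "name")
    if (!all(req %in% names(nd)))
      return(paste("nodes must have columns", paste(req, collapse = ", ")))
    if (anyDuplicated(nd$taxid))
      return("duplicated taxid")
    root <- nd$taxid[nd$taxid == nd$parent]
    if (length(root) != 1)
      return(sprintf("expected exactly one root, found %d", length(root)))
    orphan <- setdiff(nd$parent, nd$taxid)
    if (length(orphan))
      return(sprintf("orphan parent id(s): %s",
                     paste(orphan, collapse = ", ")))
    # cycle check: repeatedly map to parent; all chains must hit the root
    idx <- match(nd$parent, nd$taxid)
    cur <- seq_len(nrow(nd))
    for (step in seq_len(nrow(nd) + 1)) {
      at_root <- nd$taxid[cur] == nd$parent[cur]
      if (all(at_root)) return(TRUE)
      cur[!at_root] <- idx[cur[!at_root]]
    }
    "cycle detected in parent chain"
  })

.KNOWN_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

.parseTaxdumpLines <- function(lines) {
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load a taxdump-style taxonomy
#'
#' Parses `nodes.dmp` / `names.dmp` dialect files (fields separated by
#' `"\t|\t"`, lines terminated by `"\t|"`). Only the `taxid`, `parent` and
#' `rank` columns of the nodes file and the scientific-name rows of the names
#' file are used. Ranks other than phylum/class/order/family/genus/species
#' are mapped to `"no-rank"`. Taxa present in the nodes file but missing a
#' scientific name receive a placeholder name with a warning.
#'
#' @param nodesPath,namesPath Paths to the nodes and names files.
#' @return A [TaxonomyTable-class].
#' @export
loadTaxdump <- function(nodesPath, namesPath) {
  nl <- .parseTaxdumpLines(readLines(nodesPath))
  taxid <- as.integer(vapply(nl, `[`, "", 1L))
  parent <- as.integer(vapply(nl, `[`, "", 2L))
  rank <- vapply(nl, `[`, "", 3L)
  rank <- ifelse(rank %in% .KNOWN_RANKS, rank, "no-rank")

  ml <- .parseTaxdumpLines(readLines(namesPath))
  keep <- vapply(ml, function(x) length(x) >= 4 &&
                   trimws(x[4]) == "scientific name", logical(1))
  ml <- ml[keep]
  nm_id <- as.integer(vapply(ml, `[`, "", 1L))
  nm <- trimws(vapply(ml, `[`, "", 2L))

  name <- nm[match(taxid, nm_id)]
  if (anyNA(name)) {
    missing <- taxid[is.na(name)]
    warning(sprintf("no scientific name for taxid(s) %s; using placeholder",
                    paste(missing, collapse = ", ")))
    name[is.na(name)] <- sprintf("taxid %d", missing)
  }
  tt <- new("TaxonomyTable",
            nodes = data.frame(taxid = taxid, parent = parent, rank = rank,
                               name = name, stringsAsFactors = FALSE))
  validObject(tt)
  tt
}

#' @describeIn TaxonomyTable-class number of taxa
#' @param x A `TaxonomyTable`.
#' @export
setMethod("length", "TaxonomyTable", function(x) nrow(x@nodes))

#' Access the node table of a TaxonomyTable
#' @param x A [TaxonomyTable-class].
#' @return `data.frame` with columns taxid, parent, rank, name.
#' @export
taxonomyNodes <- function(x) x@nodes

setMethod("show", "TaxonomyTable", function(object) {
  nd <- object@nodes
  cat(sprintf("TaxonomyTable: %d taxa (%s)\n", nrow(nd),
              paste(sprintf("%d %s", tabulate(factor(nd$rank,
                levels = c(.KNOWN_RANKS, "no-rank"))),
                c(.KNOWN_RANKS, "no-rank")), collapse = ", ")))
})

#' Ranked lineage of a taxon
#'
#' Walks the parent chain from `taxid` to the root and reports the taxon
#' name at each of the five audited ranks (phylum, class, order, family,
#' genus). Ranks never encountered on the chain are returned as
#' `"unranked"`.
#'
#' @param table A [TaxonomyTable-class].
#' @param taxid Integer taxon id present in the table.
#' @return Named character vector of length 5 (`phylum` ... `genus`).
#' @examples
#' \dontrun{lineageOf(tax, 42)}
#' @export
lineageOf <- function(table, taxid) {
  nd <- table@nodes
  i <- match(taxid, nd$taxid)
  if (is.na(i))
    stop(sprintf("unknown taxid: %s", taxid))
  out <- setNames(rep("unranked", length(AUDIT_RANKS)), AUDIT_RANKS)
  repeat {
    r <- nd$rank[i]
    if (r %in% AUDIT_RANKS && out[[r]] == "unranked")
      out[[r]] <- nd$name[i]
    if (nd$parent[i] == nd$taxid[i]) break
    i <- match(nd$parent[i], nd$taxid)
  }
  out
}

#' Lineages for a vector of taxon ids
#'
#' Vectorised companion of [lineageOf()]: one row per input id, memoised so
#' repeated ids cost one chain walk.
#'
#' @param table A [TaxonomyTable-class].
#' @param taxids Integer vector of taxon ids.
#' @return `data.frame` with columns `taxid`, `phylum`, `class`, `order`,
#'   `family`, `genus`; one row per element of `taxids`.
#' @export
lineageTable <- function(table, taxids) {
  uniq <- unique(taxids)
  lin <- vapply(uniq, function(t) lineageOf(table, t),
                setNames(character(length(AUDIT_RANKS)), AUDIT_RANKS))
  lin <- t(lin)
  i <- match(taxids, uniq)
  out <- data.frame(taxid = taxids, lin[i, , drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("taxid", AUDIT_RANKS)
  out
}
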