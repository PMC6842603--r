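# Small fixtures built in code.

# write a taxdump-dialect nodes/names pair to a temp dir; rows is a list of
# c(taxid, parent, rank, name)
writeTaxdump <- function(rows, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  nodes <- vapply(rows, function(r)
    sprintf("%s\t|\t%s\t|\t%s\t|", r[1], r[2], r[3]), "")
  names_ <- vapply(rows, function(r)
    sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|", r[1], r[4]), "")
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names_, file.path(dir, "names.dmp"))
  dir
}

# lineage table for hand-built clusters; defaults give a single family
makeLineages <- function(accessions, genus,
                         family = "Famae", order = "Ordae",
                         class = "Clsae", phylum = "Phlae") {
  data.frame(accession = accessions,
             taxid = seq_along(accessions),
             phylum = rep_len(phylum, length(accessions)),
             class = rep_len(class, length(accessions)),
             order = rep_len(order, length(accessions)),
             family = rep_len(family, length(accessions)),
             genus = rep_len(genus, length(accessions)),
             stringsAsFactors = FALSE)
}

# a ClusterSet with every listed accession in one cluster
makeSingleCluster <- function(accessions, lengths = 500) {
  new("ClusterSet", threshold = 0.97, gene = "CO1",
      members = data.frame(accession = accessions, cluster = 1L,
                           centroid = accessions[1],
                           identity = c(1, rep(0.99, length(accessions) - 1)),
                           length = rep_len(lengths, length(accessions)),
                           stringsAsFactors = FALSE))
}

# small synthetic spec used across tests (~170 records)
smallSpec <- function(...) {
  simSpec(seqsPerSpecies = 5, contaminantSeqsPerGenus = 2, ...)
}

zeroRates <- c(swap = 0, dataEntry = 0, labContaminant = 0,
               pseudogene = 0, hostDiet = 0, revision = 0, bacterial = 0)
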