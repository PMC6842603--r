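# Synthetic database generator. Sequences are evolved down a generated
# taxonomy under a Jukes-Cantor-style uniform substitution process, with
# divergence targets chosen so that conspecifics co-cluster at the audit
# thresholds while congeners never do; mislabels of each cause class are
# planted at configurable rates and recorded in a truth table.

#' Settings for the synthetic database generator
#'
#' Defaults emulate the statistical structure the audit assumes: clusters of
#' highly similar sequences (>= 97%) contain conspecifics; members of
#' different genera never share a cluster. Divergences are *observed
#' pairwise* difference targets: conspecific pairs differ by at most
#' `conspecific`, congeneric species by at least `intragenus`, and genera
#' within a family by at least `interGenus`. The invariant
#' `conspecific < 1 - 0.97 <= intragenus` makes the clustering outcome exact
#' by construction.
#'
#' @param phyla,classesPerPhylum,ordersPerClass,familiesPerOrder
#'   Taxonomy shape counts (defaults 2/2/2/2).
#' @param generaPerFamily,speciesPerGenus,seqsPerSpecies More shape counts;
#'   defaults (2/1/15) give 32 genera and ~500 sequences including the
#'   contaminant block.
#' @param genes Subset of [MITO_GENES] to simulate (default `"CO1"`).
#' @param geneLengths Named integer vector of per-gene sequence lengths
#'   (inside the audit's length windows; the CO1 default, 350 bp, is at
#'   the mini-barcode scale common among partial CO1 records).
#' @param conspecific,intragenus,interGenus Pairwise divergence targets
#'   (see above).
#' @param mislabelRates Named rates (fraction of ordinary records) for each
#'   planted error class: `swap` (plain label swap, no cause signature),
#'   `dataEntry`, `labContaminant`, `pseudogene`, `hostDiet`, `revision`,
#'   `bacterial`. `bacterial` defaults to 0: bacterial records form
#'   clusters mislabeled in their entirety, outside the minority-mislabel
#'   regime the min/max estimator brackets.
#' @param swapRankWeights Sampling weights for the rank at which a plain
#'   swap is planted.
#' @param contaminantGenera Genus names for the built-in contaminant block
#'   (correctly labeled records of these genera are always included so
#'   planted contaminants have a cluster to fall into).
#' @param contaminantSeqsPerGenus Correctly labeled records per contaminant
#'   genus.
#' @param bacterialPanelSize Number of bacterial reference sequences.
#' @param indelRate Per-site indel probability for [mutateSeq()] (0 by
#'   default so identity arithmetic is exact).
#' @param accessionPrefix Two-letter accession prefix.
#' @return A list of class `"sim_spec"`.
#' @export
simSpec <- function(phyla = 2, classesPerPhylum = 2, ordersPerClass = 2,
                    familiesPerOrder = 2, generaPerFamily = 2,
                    speciesPerGenus = 1, seqsPerSpecies = 15,
                    genes = "CO1",
                    geneLengths = c(A6 = 660, A8 = 450, CO1 = 350,
                                    CO2 = 684, CO3 = 780, Cytb = 1137,
                                    ND1 = 900, ND2 = 1000, ND3 = 345,
                                    ND4 = 1300, ND4L = 290, ND5 = 1700,
                                    ND6 = 500, `12S` = 450, `16S` = 600),
                    conspecific = 0.02, intragenus = 0.08,
                    interGenus = 0.15,
                    mislabelRates = c(swap = 0.02, dataEntry = 0.005,
                                      labContaminant = 0.005,
                                      pseudogene = 0.003, hostDiet = 0.003,
                                      revision = 0.004, bacterial = 0),
                    swapRankWeights = c(phylum = 0.05, class = 0.05,
                                        order = 0.1, family = 0.2,
                                        genus = 0.6),
                    contaminantGenera = c("Homo", "Mus", "Rattus"),
                    contaminantSeqsPerGenus = 3,
                    bacterialPanelSize = 3,
                    indelRate = 0,
                    accessionPrefix = "AB") {
  spec <- list(phyla = phyla, classesPerPhylum = classesPerPhylum,
               ordersPerClass = ordersPerClass,
               familiesPerOrder = familiesPerOrder,
               generaPerFamily = generaPerFamily,
               speciesPerGenus = speciesPerGenus,
               seqsPerSpecies = seqsPerSpecies,
               genes = genes, geneLengths = geneLengths,
               conspecific = conspecific, intragenus = intragenus,
               interGenus = interGenus, mislabelRates = mislabelRates,
               swapRankWeights = swapRankWeights,
               contaminantGenera = contaminantGenera,
               contaminantSeqsPerGenus = contaminantSeqsPerGenus,
               bacterialPanelSize = bacterialPanelSize,
               indelRate = indelRate, accessionPrefix = accessionPrefix)
  class(spec) <- "sim_spec"
  .validateSimSpec(spec)
  spec
}

.validateSimSpec <- function(spec) {
  if (!(spec$conspecific < 0.03 && 0.03 <= spec$intragenus))
    stop("divergence ordering violated: need conspecific < 0.03 <= intragenus ",
         "so conspecifics co-cluster at 97% and congeners do not")
  if (spec$intragenus > spec$interGenus)
    stop("intragenus divergence must not exceed interGenus divergence")
  r <- spec$mislabelRates
  if (any(r < 0) || any(r > 1) || sum(r) > 0.5)
    stop("mislabel rates must lie in [0,1] and sum to at most 0.5")
  if (!all(spec$genes %in% MITO_GENES))
    stop("unknown gene in spec$genes")
  if (!all(spec$genes %in% names(spec$geneLengths)))
    stop("geneLengths must cover every simulated gene")
  invisible(TRUE)
}

#' Mutate a sequence under uniform substitution
#'
#' Each site is substituted independently with probability `divergence`,
#' drawing uniformly among the three other bases (a Jukes-Cantor-style
#' process observed over one branch: the expected per-site difference from
#' the input equals `divergence`). Applying the process twice yields less
#' than twice the divergence because of back-mutation. With `indelRate > 0`,
#' sites are additionally deleted or receive geometric-length insertions.
#'
#' @param seq Nucleotide sequence (character or `DNAString`).
#' @param divergence Substitution probability per site, in `[0, 1)`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param indelRate Per-site indel probability (default 0).
#' @return Character sequence.
#' @export
mutateSeq <- function(seq, divergence, seed = NULL, indelRate = 0) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  .withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
    hit <- which(runif(length(v)) < divergence)
    if (length(hit)) {
      cur <- match(v[hit], bases)
      off <- sample.int(3, length(hit), replace = TRUE)
      v[hit] <- bases[((cur - 1 + off) %% 4) + 1]
    }
    if (indelRate > 0) {
      keep <- runif(length(v)) >= indelRate / 2
      ins <- runif(length(v)) < indelRate / 2
      out <- character(0)
      for (i in seq_along(v)) {
        if (keep[i]) out <- c(out, v[i])
        if (ins[i]) out <- c(out, sample(bases, stats::rgeom(1, 0.5) + 1,
                                         replace = TRUE))
      }
      v <- out
    }
    paste(v, collapse = "")
  })
}

# branch divergence q yielding an expected observed pairwise difference d
# between two tips evolved independently from a common ancestor:
# d = 2q - (4/3) q^2
.branchFromPairwise <- function(d) {
  0.75 * (1 - sqrt(1 - (4 / 3) * d))
}

.randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute exactly k distinct sites (uniform choice among the other
# bases); used for the individual-level step so that conspecific pairwise
# differences are bounded by construction, free of binomial tails
.mutateCount <- function(seq, k) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  if (k > 0) {
    idx <- sample(length(v), k)
    cur <- match(v[idx], bases)
    off <- sample.int(3, k, replace = TRUE)
    v[idx] <- bases[((cur - 1 + off) %% 4) + 1]
  }
  paste(v, collapse = "")
}

# random capitalised names kept pairwise Levenshtein >= minDist apart
.randomNames <- function(n, existing = character(), len = 8, minDist = 3) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(sample(LETTERS, 1),
                   paste(sample(letters, len - 1, replace = TRUE),
                         collapse = ""))
    pool <- c(existing, out)
    if (length(pool) == 0 || min(adist(cand, pool)) >= minDist)
      out <- c(out, cand)
  }
  out
}

#' Generate a synthetic reference database with planted mislabels
#'
#' Builds a ranked taxonomy of the requested shape, evolves per-gene
#' sequences down it (independent random family roots; genus and species
#' models derived with branch divergences hitting the spec's pairwise
#' targets; individuals with small extra divergence and slight 3' length
#' variation), adds a correctly labeled contaminant block in its own
#' phylum, plants mislabels of each configured cause class, and records
#' everything in a truth table. Accession numbers are spaced at random
#' gaps of at least 3 so the data-entry adjacency rule can only fire on
#' deliberately planted adjacent accessions; genus names are random
#' strings kept pairwise Levenshtein distance >= 3 apart so the
#' name-similarity rule cannot fire accidentally.
#'
#' @param spec A [simSpec()] list.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An [AuditDb-class] with a complete truth table.
#' @export
simulateDatabase <- function(spec = simSpec(), seed) {
  .validateSimSpec(spec)
  if (missing(seed)) stop("a seed is required for reproducibility")
  .withSeed(seed, .simulateDatabaseImpl(spec, seed))
}

.simulateDatabaseImpl <- function(spec, seed) {
  ## ---- taxonomy ----
  nodes <- data.frame(taxid = 1L, parent = 1L, rank = "no-rank",
                      name = "root", stringsAsFactors = FALSE)
  nextId <- 2L
  addNode <- function(parent, rank, name) {
    id <- nextId
    nodes[nrow(nodes) + 1L, ] <<- list(id, as.integer(parent), rank, name)
    nextId <<- id + 1L
    id
  }
  usedNames <- spec$contaminantGenera
  newName <- function() {
    nm <- .randomNames(1, existing = usedNames)
    usedNames <<- c(usedNames, nm)
    nm
  }
  epithet <- function() paste(sample(letters, 7, replace = TRUE),
                              collapse = "")

  genusTab <- NULL
  speciesOfGenus <- list()
  familyNode <- integer()  # family name -> node id
  addGenus <- function(faId, lineageNames, gname, nSpecies, contaminant) {
    gid <- addNode(faId, "genus", gname)
    sps <- integer(nSpecies)
    spNames <- character(nSpecies)
    for (s in seq_len(nSpecies)) {
      spNames[s] <- sprintf("%s %s", gname, epithet())
      sps[s] <- addNode(gid, "species", spNames[s])
    }
    speciesOfGenus[[gname]] <<- sps
    genusTab <<- rbind(genusTab, data.frame(
      phylum = lineageNames[1], class = lineageNames[2],
      order = lineageNames[3], family = lineageNames[4], genus = gname,
      genusId = gid, familyId = faId, speciesTaxid = sps[1],
      contaminant = contaminant, stringsAsFactors = FALSE))
    gid
  }

  for (p in seq_len(spec$phyla)) {
    phName <- newName(); ph <- addNode(1L, "phylum", phName)
    for (cc in seq_len(spec$classesPerPhylum)) {
      clName <- newName(); cl <- addNode(ph, "class", clName)
      for (o in seq_len(spec$ordersPerClass)) {
        orName <- newName(); or <- addNode(cl, "order", orName)
        for (f in seq_len(spec$familiesPerOrder)) {
          faName <- newName(); fa <- addNode(or, "family", faName)
          familyNode[faName] <- fa
          for (g in seq_len(spec$generaPerFamily)) {
            addGenus(fa, c(phName, clName, orName, faName), newName(),
                     spec$speciesPerGenus, FALSE)
          }
        }
      }
    }
  }
  # contaminant block: its own phylum, correctly labeled throughout
  cphName <- newName(); cph <- addNode(1L, "phylum", cphName)
  cclName <- newName(); ccl <- addNode(cph, "class", cclName)
  corName <- newName(); cor <- addNode(ccl, "order", corName)
  cfaName <- newName(); cfa <- addNode(cor, "family", cfaName)
  familyNode[cfaName] <- cfa
  for (g in spec$contaminantGenera)
    addGenus(cfa, c(cphName, cclName, corName, cfaName), g, 1, TRUE)

  ## ---- sequences ----
  qGenus <- .branchFromPairwise(spec$interGenus)
  qSpecies <- .branchFromPairwise(spec$intragenus)
  speciesModel <- list()   # per gene: list speciesTaxid -> model sequence
  familyRoot <- list()     # per gene: named character, family -> root
  recs <- list()
  indiv <- function(model) {
    # exact site count <= L * conspecific / 2 per individual, so any two
    # conspecifics differ at <= L * conspecific sites
    kmax <- floor(nchar(model) * spec$conspecific / 2)
    s <- .mutateCount(model, sample.int(kmax + 1, 1) - 1)
    if (spec$indelRate > 0)
      s <- mutateSeq(s, 0, indelRate = spec$indelRate)
    substr(s, 1, nchar(s) - sample(0:9, 1))
  }
  for (gene in spec$genes) {
    L <- spec$geneLengths[[gene]]
    speciesModel[[gene]] <- list()
    roots <- character(0)
    for (fam in unique(genusTab$family)) {
      roots[fam] <- .randomSeq(L)
      gt <- genusTab[genusTab$family == fam, , drop = FALSE]
      for (k in seq_len(nrow(gt))) {
        gmodel <- mutateSeq(roots[fam], qGenus)
        gname <- gt$genus[k]
        nPer <- if (gt$contaminant[k]) spec$contaminantSeqsPerGenus
                else spec$seqsPerSpecies
        for (sid in speciesOfGenus[[gname]]) {
          smodel <- if (spec$speciesPerGenus > 1 || gt$contaminant[k])
            mutateSeq(gmodel, qSpecies) else gmodel
          speciesModel[[gene]][[as.character(sid)]] <- smodel
          for (r in seq_len(nPer)) {
            recs[[length(recs) + 1]] <- data.frame(
              gene = gene, trueTaxid = sid, trueGenus = gname,
              contamBlock = gt$contaminant[k], seq = indiv(smodel),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    familyRoot[[gene]] <- roots
  }
  rec <- do.call(rbind, recs)
  n <- nrow(rec)

  ## ---- accessions (random gaps >= 4, so that a planted adjacent
  ## accession at mate+1 stays >= 3 away from every other record) ----
  nums <- 100000 + cumsum(sample(4:9, n, replace = TRUE))
  rec$accession <- sprintf("%s%06d", spec$accessionPrefix, nums)
  usedNums <- nums
  rec$labeledTaxid <- rec$trueTaxid
  rec$plantedCause <- "none"
  rec$defSuffix <- ""

  ## ---- plant mislabels ----
  ordinary <- which(!rec$contamBlock)
  rates <- spec$mislabelRates
  causes <- c("swap", "dataEntry", "labContaminant", "pseudogene",
              "hostDiet", "revision", "bacterial")
  counts <- vapply(causes, function(cz)
    as.integer(round(rates[[cz]] * length(ordinary))), 0L)
  picks <- sample(ordinary, sum(counts))
  assign_ <- rep(causes, counts)

  pickTargetGenus <- function(trueGenus, rank) {
    row <- genusTab[match(trueGenus, genusTab$genus), ]
    tryRanks <- c(rank, setdiff(rev(AUDIT_RANKS), rank))
    for (r in tryRanks) {
      cand <- genusTab[!genusTab$contaminant &
                         genusTab$genus != trueGenus, , drop = FALSE]
      above <- AUDIT_RANKS[seq_len(match(r, AUDIT_RANKS) - 1)]
      for (a in above) cand <- cand[cand[[a]] == row[[a]], , drop = FALSE]
      cand <- cand[cand[[r]] != row[[r]], , drop = FALSE]
      if (nrow(cand) > 0)
        return(cand[sample.int(nrow(cand), 1), ])
    }
    stop("no relabeling target available; taxonomy too small")
  }

  synonyms <- data.frame(old = character(), current = character(),
                         stringsAsFactors = FALSE)
  bact <- vapply(seq_len(spec$bacterialPanelSize), function(i)
    .randomSeq(spec$geneLengths[[spec$genes[1]]]), "")
  names(bact) <- sprintf("bacterium%02d", seq_along(bact))

  for (k in seq_along(picks)) {
    i <- picks[k]
    cz <- assign_[k]
    if (cz == "swap") {
      rank <- sample(names(spec$swapRankWeights), 1,
                     prob = spec$swapRankWeights)
      tgt <- pickTargetGenus(rec$trueGenus[i], rank)
      rec$labeledTaxid[i] <- tgt$speciesTaxid
      rec$plantedCause[i] <- "other"
    } else if (cz == "dataEntry") {
      tgt <- pickTargetGenus(rec$trueGenus[i], "genus")
      rec$labeledTaxid[i] <- tgt$speciesTaxid
      rec$plantedCause[i] <- "data-entry"
      # adjacent accession to a conspecific cluster-mate
      # the adjacent mate must stay unplanted so its label and cluster keep
      # the planted signature intact
      mates <- setdiff(which(rec$trueTaxid == rec$trueTaxid[i]), picks)
      for (mate in mates[sample.int(length(mates))]) {
        newNum <- as.integer(sub("^[A-Za-z]+", "", rec$accession[mate])) + 1L
        if (!newNum %in% usedNums) {
          rec$accession[i] <- sprintf("%s%06d", spec$accessionPrefix, newNum)
          usedNums <- c(usedNums, newNum)
          break
        }
      }
    } else if (cz == "labContaminant") {
      cg <- genusTab[genusTab$contaminant, , drop = FALSE]
      src <- cg[sample.int(nrow(cg), 1), ]
      rec$trueTaxid[i] <- src$speciesTaxid
      rec$trueGenus[i] <- src$genus
      rec$seq[i] <- indiv(speciesModel[[rec$gene[i]]][[
        as.character(src$speciesTaxid)]])
      rec$plantedCause[i] <- "lab-contaminant"
    } else if (cz == "pseudogene") {
      tgt <- pickTargetGenus(rec$trueGenus[i], "genus")
      rec$labeledTaxid[i] <- tgt$speciesTaxid
      rec$plantedCause[i] <- "pseudogene"
      rec$defSuffix[i] <- " (pseudogene)"
    } else if (cz == "hostDiet") {
      tgt <- pickTargetGenus(rec$trueGenus[i], "genus")
      rec$trueTaxid[i] <- tgt$speciesTaxid
      rec$trueGenus[i] <- tgt$genus
      rec$seq[i] <- indiv(speciesModel[[rec$gene[i]]][[
        as.character(tgt$speciesTaxid)]])
      rec$plantedCause[i] <- "host-or-diet"
      rec$defSuffix[i] <- ", from gut content analysis"
    } else if (cz == "revision") {
      trueGenus <- rec$trueGenus[i]
      row <- genusTab[match(trueGenus, genusTab$genus), ]
      legacy <- newName()
      gid <- addNode(row$familyId, "genus", legacy)
      sid <- addNode(gid, "species", sprintf("%s %s", legacy, epithet()))
      synonyms <- rbind(synonyms, data.frame(
        old = legacy, current = trueGenus, stringsAsFactors = FALSE))
      rec$labeledTaxid[i] <- sid
      rec$plantedCause[i] <- "taxonomic-revision"
    } else if (cz == "bacterial") {
      src <- sample(seq_along(bact), 1)
      s <- mutateSeq(bact[[src]], 0.01)
      rec$seq[i] <- substr(s, 1, nchar(s) - sample(0:9, 1))
      rec$trueTaxid[i] <- NA_integer_
      rec$trueGenus[i] <- NA_character_
      rec$plantedCause[i] <- "bacterial"
    }
  }

  ## ---- assemble objects ----
  tax <- new("TaxonomyTable", nodes = nodes)
  validObject(tax)

  labLin <- lineageTable(tax, rec$labeledTaxid)
  okTrue <- !is.na(rec$trueTaxid)
  trueLin <- labLin
  trueLin[] <- NA
  trueLin[okTrue, ] <- lineageTable(tax, rec$trueTaxid[okTrue])
  trueLin[!okTrue, AUDIT_RANKS] <- "Bacteria"
  spName <- function(taxids) {
    out <- nodes$name[match(taxids, nodes$taxid)]
    out[is.na(taxids)] <- "Bacteria sp."
    out
  }

  differs <- vapply(seq_len(n), function(i) {
    for (r in AUDIT_RANKS)
      if (!identical(trueLin[[r]][i], labLin[[r]][i])) return(r)
    NA_character_
  }, "")
  isMis <- !is.na(differs)

  definition <- sprintf("%s mitochondrial %s gene, partial cds%s.",
                        spName(rec$labeledTaxid), rec$gene, rec$defSuffix)

  meta <- data.frame(accession = rec$accession, taxid = rec$labeledTaxid,
                     gene = rec$gene, definition = definition,
                     stringsAsFactors = FALSE)
  truth <- data.frame(
    accession = rec$accession, gene = rec$gene,
    taxid = rec$labeledTaxid, definition = definition,
    stringsAsFactors = FALSE)
  for (r in AUDIT_RANKS) truth[[paste0("true_", r)]] <- trueLin[[r]]
  truth$true_species <- spName(rec$trueTaxid)
  for (r in AUDIT_RANKS) truth[[paste0("lab_", r)]] <- labLin[[r]]
  truth$lab_species <- spName(rec$labeledTaxid)
  truth$isMislabeled <- isMis
  truth$plantedCause <- rec$plantedCause
  truth$plantedRank <- differs

  seqs <- Biostrings::DNAStringSet(setNames(rec$seq, rec$accession))

  refs <- list()
  for (gene in spec$genes) {
    roots <- familyRoot[[gene]]
    if (gene %in% PROTEIN_GENES) {
      aa <- vapply(roots, function(s)
        as.character(translateFrame(s, 0, "5")), "")
      refs[[gene]] <- Biostrings::AAStringSet(setNames(aa, names(roots)))
    } else {
      refs[[gene]] <- Biostrings::DNAStringSet(roots)
    }
  }

  resolvedSpec <- unclass(spec)
  resolvedSpec$seed <- seed
  db <- new("AuditDb", seqs = seqs, meta = meta, taxonomy = tax,
            refs = refs, truth = truth, synonyms = synonyms,
            bacterial = Biostrings::DNAStringSet(bact),
            simSpec = resolvedSpec)
  validObject(db)
  db
}

#' Planted mislabel totals by rank
#'
#' Cumulative counts of truth-table mislabels at or above each audited
#' rank: a record whose labels first disagree at rank r is counted at r and
#' at every rank below it. Optionally restricted to a set of accessions
#' (e.g. the sequences in multisequence clusters, the estimator's
#' denominator universe).
#'
#' @param truth Truth table of an [AuditDb-class].
#' @param accessions Optional accession subset.
#' @return Named integer vector over [AUDIT_RANKS].
#' @export
plantedTotals <- function(truth, accessions = NULL) {
  if (!is.null(accessions))
    truth <- truth[truth$accession %in% accessions, , drop = FALSE]
  out <- setNames(integer(length(AUDIT_RANKS)), AUDIT_RANKS)
  for (k in seq_along(AUDIT_RANKS)) {
    r <- AUDIT_RANKS[k]
    hit <- !is.na(truth$plantedRank) &
      match(truth$plantedRank, AUDIT_RANKS) <= k
    out[r] <- sum(hit)
  }
  out
}
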