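test_that("mutateSeq hits its expected divergence and saturates", {
  s <- randomDna(1000)
  expect_identical(mutateSeq(s, 0), s)
  # binomial sampling check over 200 seeds
  obs <- vapply(1:200, function(k) {
    m <- mutateSeq(s, 0.1, seed = 9000 + k)
    mean(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  }, 0)
  expect_lt(abs(mean(obs) - 0.1), 0.02)
  # back-mutation: two rounds at d diverge less than 2d
  twice <- vapply(1:50, function(k) {
    m <- mutateSeq(mutateSeq(s, 0.3, seed = k), 0.3, seed = 5000 + k)
    mean(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  }, 0)
  expect_lt(mean(twice), 0.55)
  expect_gt(mean(twice), 0.40)
  expect_error(mutateSeq(s, 1.2), "divergence")
})

test_that("indel mode changes sequence length", {
  s <- randomDna(500)
  m <- mutateSeq(s, 0.01, seed = 3, indelRate = 0.05)
  expect_false(nchar(m) == nchar(s) &&
                 identical(strsplit(m, "")[[1]], strsplit(s, "")[[1]]))
})

test_that("spec validation enforces the divergence ordering and rates", {
  expect_error(simSpec(conspecific = 0.05), "divergence ordering")
  expect_error(simSpec(intragenus = 0.5, interGenus = 0.2), "intragenus")
  expect_error(simSpec(mislabelRates = c(swap = 0.6, dataEntry = 0,
                                         labContaminant = 0, pseudogene = 0,
                                         hostDiet = 0, revision = 0,
                                         bacterial = 0)), "rates")
  expect_error(simulateDatabase(simSpec()), "seed")
})

test_that("truth tables are internally consistent", {
  db <- simulateDatabase(smallSpec(), seed = 612)
  tr <- dbTruth(db)
  # mislabel flag <=> lineages disagree at some audited rank
  disagree <- rowSums(sapply(AUDIT_RANKS, function(r)
    tr[[paste0("true_", r)]] != tr[[paste0("lab_", r)]])) > 0
  expect_equal(tr$isMislabeled, disagree)
  # planted rank is the highest disagreeing rank
  for (i in which(tr$isMislabeled)) {
    first <- AUDIT_RANKS[which(sapply(AUDIT_RANKS, function(r)
      tr[[paste0("true_", r)]][i] != tr[[paste0("lab_", r)]][i]))[1]]
    expect_equal(tr$plantedRank[i], first)
  }
  expect_true(all(tr$plantedCause[!tr$isMislabeled] == "none"))
  # labeled lineage comes from the labeled taxid via the taxonomy
  lin <- dbLineages(db)
  expect_equal(lin$genus, tr$lab_genus)
})

test_that("divergence structure separates genera and unites conspecifics", {
  db <- simulateDatabase(smallSpec(), seed = 613)
  tr <- dbTruth(db)
  clean <- tr$accession[!tr$isMislabeled]
  seqs <- dbSeqs(db)
  set.seed(613)
  sp <- tr$true_species[match(clean, tr$accession)]
  gn <- tr$true_genus[match(clean, tr$accession)]
  # conspecific pairs: identity >= 0.97
  conIds <- c()
  for (s in unique(sp)) {
    accs <- clean[sp == s]
    if (length(accs) < 2) next
    pick <- accs[sample(length(accs), 2)]
    conIds <- c(conIds, pairwiseIdentity(seqs[[pick[1]]], seqs[[pick[2]]]))
  }
  expect_true(all(conIds >= 0.97))
  # inter-genus pairs: identity < 0.97
  gens <- unique(gn)
  interIds <- vapply(1:20, function(k) {
    g2 <- sample(gens, 2)
    a <- sample(clean[gn == g2[1]], 1)
    b <- sample(clean[gn == g2[2]], 1)
    pairwiseIdentity(seqs[[a]], seqs[[b]])
  }, 0)
  expect_true(all(interIds < 0.97))
})

test_that("zero mislabel rates give a fully concordant clustering", {
  db <- simulateDatabase(smallSpec(mislabelRates = zeroRates), seed = 614)
  expect_true(all(!dbTruth(db)$isMislabeled))
  cs <- greedyCluster(dbSeqs(db), 0.97, gene = "CO1")
  est <- aggregateMislabels(cs, dbLineages(db), seqs = dbSeqs(db))
  expect_true(all(est$maxRate == 0))
})

test_that("three planted genus swaps are pinned exactly by resolution", {
  # 5 genera x 10 sequences; swap three records (in different clusters)
  # to a sister genus, all minorities
  sp <- simSpec(phyla = 1, classesPerPhylum = 1, ordersPerClass = 1,
                familiesPerOrder = 1, generaPerFamily = 5,
                speciesPerGenus = 1, seqsPerSpecies = 10,
                contaminantSeqsPerGenus = 1,
                mislabelRates = zeroRates)
  db <- simulateDatabase(sp, seed = 615)
  meta <- dbMeta(db)
  tax <- dbTaxonomy(db)
  lin0 <- dbLineages(db)
  genera <- unique(lin0$genus[!lin0$genus %in%
                                c("Homo", "Mus", "Rattus")])
  swapped <- character(0)
  for (k in 1:3) {
    from <- genera[k]; to <- genera[k + 1]
    victim <- which(lin0$genus == from)[1]
    target <- meta$taxid[match(TRUE, lin0$genus == to)]
    meta$taxid[victim] <- target
    swapped <- c(swapped, meta$accession[victim])
  }
  db2 <- new("AuditDb", seqs = dbSeqs(db), meta = meta, taxonomy = tax,
             refs = dbRefs(db), truth = dbTruth(db),
             synonyms = dbSynonyms(db), bacterial = dbBacterial(db),
             simSpec = db@simSpec)
  cs <- greedyCluster(dbSeqs(db2), 0.97, gene = "CO1")
  est <- aggregateMislabels(cs, dbLineages(db2), seqs = dbSeqs(db2),
                            largeMin = 5)
  g <- est[est$rank == "genus", ]
  expect_equal(g$minCount, 3L)
  expect_equal(g$maxCount, 3L)
})

test_that("written spec.json records the resolved settings and seed", {
  db <- simulateDatabase(smallSpec(), seed = 616)
  dir <- tempfile()
  writeAuditDb(db, dir)
  sp <- jsonlite::read_json(file.path(dir, "spec.json"),
                            simplifyVector = TRUE)
  expect_equal(sp$seed, 616)
  expect_equal(sp$genes, "CO1")
})
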