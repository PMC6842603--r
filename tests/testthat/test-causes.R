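test_that("windowed identity profiles expose chimeric structure", {
  set.seed(91)
  ref <- randomDna(400)
  # identical: flat at 1
  p1 <- windowedIdentityProfile(ref, ref, window = 60, step = 30)
  expect_true(all(p1$identity == 1))
  expect_gt(nrow(p1), 5)
  # chimera: first half identical, second half random
  chim <- paste0(substr(ref, 1, 200), randomDna(200))
  p2 <- windowedIdentityProfile(chim, ref, window = 60, step = 30)
  expect_gt(max(p2$identity) - min(p2$identity), 0.3)
  # window covering everything collapses to the overall identity
  p3 <- windowedIdentityProfile(chim, ref, window = 10000, step = 30)
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$identity, pairwiseIdentity(chim, ref), tolerance = 0.02)
})

# shared context: a cluster of 6 Gcons members plus one flagged record
causeFixture <- function(flaggedLabel = "Gelse", accession = "XY900001",
                         flaggedSeq = NULL, definition = "mito record",
                         phylum = "Phlae") {
  set.seed(17)
  model <- randomDna(400)
  accs <- c(sprintf("XY%06d", seq(100, 600, by = 100)), accession)
  seqs <- setNames(
    c(replicate(6, seqTaxAudit:::.mutateCount(model, sample(0:2, 1))),
      if (is.null(flaggedSeq)) seqTaxAudit:::.mutateCount(model, 1)
      else flaggedSeq), accs)
  lin <- makeLineages(accs, genus = c(rep("Gcons", 6), flaggedLabel),
                      phylum = phylum)
  defs <- setNames(rep("mitochondrial CO1 gene", 7), accs)
  defs[accession] <- definition
  list(accs = accs, seqs = seqs, lin = lin, defs = defs, model = model)
}

test_that("nearly consecutive accessions of another genus mean data entry", {
  fx <- causeFixture(accession = "XY000101")
  fx$lin$genus[1] <- "Gother"
  fx$accs[1] <- "XY000100"
  names(fx$seqs)[1] <- "XY000100"
  fx$lin$accession[1] <- "XY000100"
  names(fx$defs)[1] <- "XY000100"
  ca <- classifyCause("XY000101", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "data-entry")
  expect_match(ca$evidence, "adjacent")
})

test_that("a very similar genus name also means data entry", {
  fx <- causeFixture(flaggedLabel = "Gcoms")
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "data-entry")
  expect_match(ca$evidence, "edit distance")
})

test_that("clusters whose consensus is a contaminant genus fire rule 2", {
  fx <- causeFixture()
  fx$lin$genus[1:6] <- "Homo"
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "lab-contaminant")
})

test_that("pseudogene keyword beats the profile branch", {
  fx <- causeFixture(definition = "CO1 pseudogene, mitochondrion")
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "pseudogene")
  expect_match(ca$evidence, "keyword")
})

test_that("a chimeric identity profile fires the pseudogene rule", {
  fx0 <- causeFixture()
  chim <- paste0(substr(fx0$model, 1, 200), randomDna(200))
  fx <- causeFixture(flaggedSeq = chim)
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "pseudogene")
  expect_match(ca$evidence, "drop")
})

test_that("gut-content keywords mean host or dietary contamination", {
  fx <- causeFixture(definition = "CO1, from gut content analysis")
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "host-or-diet")
})

test_that("sequences closer to the bacterial panel are called bacterial", {
  set.seed(23)
  bact <- randomDna(400)
  fx <- causeFixture(flaggedSeq = seqTaxAudit:::.mutateCount(bact, 2))
  conf <- causeConfig(bacterialPanel = Biostrings::DNAStringSet(bact))
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs, conf)
  expect_equal(ca$cause, "bacterial")
})

test_that("synonym-table hits are taxonomic revisions", {
  fx <- causeFixture(flaggedLabel = "Vetustus")
  conf <- causeConfig(synonyms = data.frame(old = "Vetustus",
                                            current = "Gcons",
                                            stringsAsFactors = FALSE))
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs, conf)
  expect_equal(ca$cause, "taxonomic-revision")
})

test_that("records with no matching rule fall through to other", {
  fx <- causeFixture()
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "other")
})

test_that("Porifera and Cnidaria members are not assessed", {
  fx <- causeFixture(phylum = "Porifera")
  ca <- classifyCause("XY900001", fx$accs, fx$lin, fx$seqs, fx$defs)
  expect_equal(ca$cause, "not-assessed")
})

test_that("cause calls are invariant to member order", {
  fx <- causeFixture(definition = "CO1, parasite study material")
  set.seed(4)
  for (k in 1:5) {
    ord <- sample(length(fx$accs))
    ca <- classifyCause("XY900001", fx$accs[ord], fx$lin, fx$seqs,
                        fx$defs)
    expect_equal(ca$cause, "host-or-diet")
  }
})

test_that("planted causes are recovered with high recall", {
  sp <- simSpec(mislabelRates = c(swap = 0, dataEntry = 0.05,
                                  labContaminant = 0.05, pseudogene = 0.05,
                                  hostDiet = 0.05, revision = 0.03,
                                  bacterial = 0))
  calls <- list()
  for (sd in 1:8) {
    db <- simulateDatabase(sp, seed = 7000 + sd)
    cs <- greedyCluster(dbSeqs(db), 0.97, gene = "CO1")
    m <- clusterMembers(cs)
    lin <- dbLineages(db)
    tr <- dbTruth(db)
    cconf <- causeConfig(bacterialPanel = dbBacterial(db),
                         synonyms = dbSynonyms(db))
    defs <- setNames(dbMeta(db)$definition, dbMeta(db)$accession)
    for (cid in multiClusters(cs)) {
      accs <- m$accession[m$cluster == cid]
      if (!"genus" %in% flagDiscordant(accs, lin)$discordant) next
      idm <- identityMatrix(dbSeqs(db)[accs])
      res <- resolveMislabels(accs, lin, "genus", idm)
      for (acc in names(res)[!is.na(res) & res == "mislabeled"]) {
        ca <- classifyCause(acc, accs, lin, dbSeqs(db), defs, cconf,
                            idmat = idm)
        calls[[length(calls) + 1]] <- data.frame(
          truth = tr$plantedCause[match(acc, tr$accession)],
          call = ca$cause, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, calls)
  for (cz in c("data-entry", "lab-contaminant", "pseudogene",
               "host-or-diet")) {
    sub <- calls[calls$truth == cz, ]
    expect_gte(nrow(sub), 150)
    expect_gte(mean(sub$call == cz), 0.9)
  }
})
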