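test_that("discordance is detected per rank, unranked members excluded", {
  lin <- makeLineages(sprintf("A%02d", 1:5), genus = "Apis")
  rep_ <- flagDiscordant(lin$accession, lin)
  expect_equal(rep_$discordant, character(0))

  lin2 <- makeLineages(sprintf("B%02d", 1:5),
                       genus = c("Apis", "Apis", "Apis", "Bombus", "Bombus"))
  rep2 <- flagDiscordant(lin2$accession, lin2)
  expect_equal(rep2$discordant, "genus")
  expect_equal(sort(names(rep2$counts$genus)), c("Apis", "Bombus"))

  # an arthropod/chordate mix is discordant at all five ranks
  lin3 <- rbind(
    makeLineages(c("C1", "C2"), genus = "Apis", family = "Apidae",
                 order = "Hymenoptera", class = "Insecta",
                 phylum = "Arthropoda"),
    makeLineages("C3", genus = "Danio", family = "Cyprinidae",
                 order = "Cypriniformes", class = "Actinopteri",
                 phylum = "Chordata"))
  expect_equal(flagDiscordant(lin3$accession, lin3)$discordant, AUDIT_RANKS)

  # unranked members do not fabricate discordance
  lin4 <- makeLineages(c("D1", "D2", "D3"), genus = c("Apis", "Apis",
                                                      "unranked"))
  expect_equal(flagDiscordant(lin4$accession, lin4)$discordant, character(0))
  expect_equal(sum(flagDiscordant(lin4$accession, lin4)$counts$genus), 2)
})

test_that("min/max bounds reproduce the worked example and edge cases", {
  b <- minMaxMislabels(c(A = 3, B = 2, C = 1))
  expect_identical(b$min, 3L)
  expect_identical(b$max, 5L)
  expect_identical(minMaxMislabels(c(A = 4))[c("min", "max")],
                   list(min = 0L, max = 0L))
  b2 <- minMaxMislabels(c(A = 2, B = 2))
  expect_identical(c(b2$min, b2$max), c(2L, 2L))
})

test_that("min/max bounds equal exhaustive hypothesis enumeration", {
  taxa <- c("A", "B", "C", "D")
  for (n in 1:8) {
    for (parts in allCountMultisets(n, 4)) {
      counts <- setNames(parts, taxa[seq_along(parts)])
      got <- minMaxMislabels(counts)
      want <- oracleMinMax(counts)
      expect_identical(c(got$min, got$max), unname(want),
                       info = paste(counts, collapse = ","))
      expect_true(got$min <= got$max)
      if (length(counts) > 1)
        expect_true(got$max <= sum(counts) - 1)
    }
  }
})

test_that("the similarity consensus resolves a planted minority mislabel", {
  set.seed(77)
  model <- randomDna(400)
  seqs <- setNames(
    c(replicate(9, seqTaxAudit:::.mutateCount(model, sample(0:2, 1))),
      seqTaxAudit:::.mutateCount(model, 1)),
    sprintf("R%02d", 1:10))
  lin <- makeLineages(names(seqs),
                      genus = c(rep("Gvera", 9), "Gwronga"))
  idm <- identityMatrix(seqs)
  res <- resolveMislabels(names(seqs), lin, "genus", idm)
  expect_equal(unname(res[10]), "mislabeled")
  expect_true(all(res[1:9] == "correct"))
})

test_that("two indistinguishable label groups stay unresolved", {
  s <- randomDna(300)
  seqs <- setNames(rep(s, 4), c("S1", "S2", "S3", "S4"))
  lin <- makeLineages(names(seqs), genus = c("Ga", "Ga", "Gb", "Gb"))
  idm <- identityMatrix(seqs)
  res <- resolveMislabels(names(seqs), lin, "genus", idm)
  expect_true(all(res == "unresolved"))
  expect_error(resolveMislabels(c("S1", "S2"),
                                makeLineages(c("S1", "S2"), genus = "Ga"),
                                "genus", idm), "not discordant")
})

test_that("a genuinely distinct minority group is called correct", {
  set.seed(31)
  mA <- randomDna(300)
  mB <- mutateSeq(mA, 0.10)
  seqs <- setNames(
    c(replicate(6, seqTaxAudit:::.mutateCount(mA, sample(0:2, 1))),
      replicate(3, seqTaxAudit:::.mutateCount(mB, sample(0:2, 1)))),
    sprintf("T%02d", 1:9))
  lin <- makeLineages(names(seqs), genus = c(rep("Ga", 6), rep("Gb", 3)))
  res <- resolveMislabels(names(seqs), lin, "genus", identityMatrix(seqs))
  expect_true(all(res[7:9] == "correct"))
  expect_true(all(res[1:6] == "correct"))
})

test_that("aggregation reproduces the worked-example rates", {
  accs <- sprintf("W%02d", 1:6)
  seqs <- setNames(rep(randomDna(300), 6), accs)
  lin <- makeLineages(accs, genus = c("A", "A", "A", "B", "B", "C"))
  cs <- greedyCluster(seqs, 0.97)
  expect_equal(length(cs), 1L)
  est <- aggregateMislabels(cs, lin, seqs = seqs, largeMin = 100)
  g <- est[est$rank == "genus", ]
  expect_equal(g$minCount, 3L)
  expect_equal(g$maxCount, 5L)
  expect_equal(g$minRate, 50)
  expect_equal(g$maxRate, 83.33, tolerance = 1e-3)
  expect_equal(g$denominator, 6)
})

test_that("no discordant clusters means zero rates everywhere", {
  accs <- sprintf("Z%02d", 1:6)
  seqs <- setNames(rep(randomDna(300), 6), accs)
  lin <- makeLineages(accs, genus = "A")
  est <- aggregateMislabels(greedyCluster(seqs, 0.97), lin, seqs = seqs)
  expect_true(all(est$minRate == 0) && all(est$maxRate == 0))
})

test_that("a phylum-level error counts cumulatively at every rank", {
  phy <- makeLineages("P1", genus = "Gfar", family = "Ffar",
                      order = "Ofar", class = "Cfar", phylum = "Pfar")
  lin <- rbind(makeLineages(c("P2", "P3"), genus = "Gnear"), phy)
  base <- randomDna(300)
  seqs <- setNames(rep(base, 3), c("P2", "P3", "P1"))
  # second, concordant cluster
  other <- setNames(replicate(2, paste0(randomDna(300))), c("P4", "P5"))
  other[2] <- other[[1]]
  lin <- rbind(lin, makeLineages(c("P4", "P5"), genus = "Gother"))
  cs <- greedyCluster(c(seqs, other), 0.97)
  expect_equal(length(cs), 2L)
  est <- aggregateMislabels(cs, lin, seqs = c(seqs, other))
  expect_equal(est$minCount, rep(1L, 5))
  expect_equal(est$minRate, rep(20, 5))  # denominator 5
  # exclusive view: the error sits at phylum only
  estEx <- aggregateMislabels(cs, lin, seqs = c(seqs, other),
                              cumulative = FALSE)
  expect_equal(estEx$minCount, c(1L, 0L, 0L, 0L, 0L))
})

test_that("rank rates are monotone down the hierarchy on synthetic data", {
  db <- simulateDatabase(smallSpec(), seed = 88)
  cs <- greedyCluster(dbSeqs(db), 0.97, gene = "CO1")
  est <- aggregateMislabels(cs, dbLineages(db), seqs = dbSeqs(db))
  expect_true(all(diff(est$minRate) >= 0))
  expect_true(all(diff(est$maxRate) >= 0))
  expect_true(all(est$minRate <= est$maxRate))
})

test_that("full resolution replaces the bracket for large clusters", {
  set.seed(55)
  model <- randomDna(300)
  accs <- sprintf("L%02d", 1:10)
  seqs <- setNames(
    c(replicate(9, seqTaxAudit:::.mutateCount(model, sample(0:2, 1))),
      seqTaxAudit:::.mutateCount(model, 1)), accs)
  lin <- makeLineages(accs, genus = c(rep("Ga", 9), "Gb"))
  cs <- greedyCluster(seqs, 0.97)
  # below the size cutoff: bounds {9,1} -> min 1, max 9
  est1 <- aggregateMislabels(cs, lin, seqs = seqs, largeMin = 100)
  g1 <- est1[est1$rank == "genus", ]
  expect_equal(c(g1$minCount, g1$maxCount), c(1L, 9L))
  # at or above the cutoff: resolver pins the count exactly
  est2 <- aggregateMislabels(cs, lin, seqs = seqs, largeMin = 10)
  g2 <- est2[est2$rank == "genus", ]
  expect_equal(c(g2$minCount, g2$maxCount), c(1L, 1L))
  expect_equal(attr(est2, "details")$status, "resolved")
})
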