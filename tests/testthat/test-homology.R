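# Homology control: identity, greedy clustering, and leakage-free splits.

test_that("pairwise identity matches definition on constructed pairs", {
  expect_equal(pairwiseIdentity("ACGU", "ACGU"), 1)
  expect_equal(pairwiseIdentity("AAAA", "CCCC"), 0)
  # shorter-sequence denominator: a contained subsequence scores 1
  expect_equal(pairwiseIdentity("ACG", "AACCGG"), 1)
  # symmetric
  expect_equal(pairwiseIdentity("ACGGUA", "AGGU"),
               pairwiseIdentity("AGGU", "ACGGUA"))
  expect_error(pairwiseIdentity("", "ACGU"), "empty")
})

test_that("identity agrees with a global-alignment oracle on random pairs", {
  set.seed(79)
  for (i in 1:80) {
    a <- randRna(sample(18:26, 1))
    b <- randRna(sample(18:26, 1))
    expect_equal(pairwiseIdentity(a, b), oracleIdentity(a, b),
                 info = paste(a, b))
  }
})

test_that("greedy clustering separates letter-disjoint families and merges mutants", {
  fam <- c(ac = strrep("AC", 11), gu = strrep("GU", 11),
           ag = strrep("AG", 11), cu = strrep("CU", 11))
  cl <- clusterMirnas(fam, threshold = 0.70)
  expect_length(cl, 4L)

  # a near-copy joins its parent's cluster
  set.seed(83)
  parent <- randRna(22)
  chars <- strsplit(parent, "")[[1]]
  idx <- sample(22, 2)
  for (j in idx) chars[j] <- setdiff(c("A", "C", "G", "U"), chars[j])[1]
  seqs <- c(p = parent, child = paste(chars, collapse = ""),
            far = strrep("AC", 11))
  cl2 <- clusterMirnas(seqs, threshold = 0.85)
  sizes <- sort(lengths(cl2))
  expect_equal(unname(sizes), c(1L, 2L))
  both <- cl2[[which(lengths(cl2) == 2L)]]
  expect_setequal(both, c("p", "child"))
})

test_that("every cluster member reaches its representative's threshold", {
  set.seed(89)
  seqs <- setNames(vapply(1:30, function(i) randRna(sample(20:24, 1)), ""),
                   paste0("m", 1:30))
  cl <- clusterMirnas(seqs, threshold = 0.75)
  expect_setequal(unlist(cl), names(seqs))
  for (members in cl) {
    rep <- seqs[[members[1]]]
    for (m in members[-1])
      expect_gte(pairwiseIdentity(seqs[[m]], rep), 0.75)
  }
})

test_that("makeSplit holds out the test species and removes homologous training miRNAs", {
  set.seed(97)
  base <- randRna(22)
  chars <- strsplit(base, "")[[1]]
  chars[5] <- setdiff(c("A", "C", "G", "U"), chars[5])[1]
  mut <- paste(chars, collapse = "")  # ~0.95 identity to base
  mir <- c(gma1 = base, osa1 = mut, osa2 = strrep("AC", 11),
           osa3 = strrep("GU", 11))
  ex <- toyExamples(nPos = 8, nNeg = 8, seed = 97)
  ex$mirna_id <- rep(names(mir), each = 4)
  ex$species <- c(rep("gma", 4), rep("osa", 12))

  sp <- makeSplit(ex, mir, testSpecies = "gma", threshold = 0.70)
  expect_true(all(testExamples(sp)$species == "gma"))
  # osa1 is homologous to the only test miRNA; all 4 of its rows go
  expect_equal(unname(sp@removed["train_homologs"]), 4L)
  expect_false("osa1" %in% trainExamples(sp)$mirna_id)
  expect_lt(auditSplit(sp, mir), 0.70)
  expect_error(makeSplit(ex, mir, testSpecies = "zma"), "absent")
})

test_that("exact duplicate test feature vectors are removed, first kept", {
  mir <- c(a = strrep("AC", 11), b = strrep("GU", 11))
  ex <- toyExamples(nPos = 4, nNeg = 4, seed = 5)
  ex$mirna_id <- rep(c("a", "b"), 4)
  ex$species <- "gma"
  dupd <- rbind(ex, ex[1, ], ex[1, ])  # two exact copies of row 1
  sp <- makeSplit(dupd, mir, testSpecies = "gma")
  expect_equal(unname(sp@removed["test_duplicates"]), 2L)
  expect_equal(nrow(testExamples(sp)), nrow(ex))
})

test_that("excludeLike drops test examples resembling the exclusion list", {
  mir <- c(a = strrep("AC", 11), b = strrep("GU", 11))
  ex <- toyExamples(nPos = 4, nNeg = 4, seed = 7)
  ex$mirna_id <- rep(c("a", "b"), 4)
  ex$species <- c(rep("gma", 4), rep("osa", 4))
  sp <- makeSplit(ex, mir, testSpecies = "gma",
                  excludeLike = c(strrep("AC", 11)))
  # both test miRNAs appear in gma rows; only "a" matches the exclusion
  kept <- testExamples(sp)$mirna_id
  expect_false("a" %in% kept)
  expect_gte(unname(sp@removed["test_excluded"]), 1L)
})
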