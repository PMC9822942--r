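# The 11-feature extractor and its pairing-derived components.

pv <- function(x) c("UNPAIRED", "WC")[x + 1L]  # 0/1 -> pairing states

test_that("longest consecutive pairing run matches definition and oracle", {
  expect_equal(longestConsecutivePairings(pv(c(1, 1, 0, 1, 1, 1))),
               c(length = 3, pos = 4))
  expect_equal(longestConsecutivePairings(pv(rep(0, 21))),
               c(length = 0, pos = 0))
  # ties go to the smallest start
  expect_equal(longestConsecutivePairings(pv(c(1, 1, 0, 1, 1)))[["pos"]], 1)
  expect_error(longestConsecutivePairings(character(0)), "empty")

  set.seed(41)
  for (i in 1:300) {
    paired <- runif(sample(16:30, 1)) < 0.5
    expect_equal(longestConsecutivePairings(pv(paired)),
                 oracleLongestRun(paired))
  }
})

test_that("AU content counts A/U in the flanked, clipped window", {
  expect_equal(auContent("AUAUAU", 1, 6, flank = 0), 1.0)
  expect_equal(auContent("GCGC", 1, 4, flank = 0), 0.0)
  expect_equal(auContent("AUGC", 1, 4, flank = 0), 0.5)
  # flank clipped at the transcript start
  expect_equal(auContent("GGAUAUGG", 3, 6, flank = 10), 4 / 8)
})

test_that("m/e motif score is 1 on the profile, 0 on its complement, Hamming otherwise", {
  L <- 21
  profile <- rep(FALSE, L)
  profile[c(2:8, 13:16)] <- TRUE
  expect_equal(meMotif(pv(profile)), 1.0)
  expect_equal(meMotif(pv(!profile)), 0.0)
  set.seed(43)
  for (i in 1:100) {
    paired <- runif(L) < 0.5
    expect_equal(meMotif(pv(paired)), mean(paired == profile))
  }
})

test_that("a perfect 21-nt duplex forces every pairing count", {
  mir <- c(m1 = "UGUCGUAAGGAUUUCAGGUAU")
  tx <- c(t1 = paste0(randRna(50), revComp(mir[["m1"]]), randRna(50)))
  d <- alignDuplex(mir[["m1"]], substr(tx[["t1"]], 51, 71),
                   mirnaId = "m1", transcriptId = "t1", siteOffset = 50L)
  f <- extractFeatures(d, mir, tx)
  expect_length(f, 11L)
  expect_named(f, targetFeatureNames())
  expect_equal(unname(f["seed_match"]), 7)
  expect_equal(unname(f["n_paired"]), 21)
  expect_equal(unname(f["longest_run"]), 21)
  expect_equal(unname(f["longest_run_pos"]), 1)
  expect_equal(unname(f["n_paired_3p"]), 9)
  expect_equal(unname(f["seed_minus_3p"]), -2)
  expect_equal(unname(f["site_length"]), 21)
  expect_lt(f["folding_energy"], 0)
  expect_true(all(f[c("accessibility", "au_content", "me_motif")] >= 0 &
                  f[c("accessibility", "au_content", "me_motif")] <= 1))
})

test_that("a pairless duplex yields the degenerate feature vector", {
  d <- alignDuplex(strrep("A", 21), strrep("A", 21))
  f <- extractFeatures(d, strrep("A", 21), strrep("A", 21))
  expect_equal(unname(f[c("n_paired", "folding_energy", "seed_match",
                          "seed_minus_3p")]), c(0, 0, 0, 0))
  expect_length(f, 11L)
})

test_that("pairing-count identities hold on random vectors", {
  set.seed(47)
  for (i in 1:200) {
    paired <- runif(sample(16:30, 1)) < runif(1)
    counts <- phytomir:::.pairingCounts(pv(paired))
    oc <- oraclePairingCounts(paired)
    expect_equal(unname(counts["seed_match"]), oc$seed_match)
    expect_equal(unname(counts["n_paired"]), oc$n_paired)
    expect_equal(unname(counts["n_paired_3p"]), oc$n_paired_3p)
    expect_equal(unname(counts["seed_minus_3p"]),
                 unname(counts["seed_match"] - counts["n_paired_3p"]))
    expect_lte(counts["longest_run"], counts["n_paired"])
    expect_lte(counts["n_paired"], length(paired))
  }
})

test_that("accessibility is 1 in unstructured context and low inside a hairpin stem", {
  expect_equal(accessibility(strrep("A", 150), 60, 80), 1.0,
               tolerance = 1e-6)
  # 20-bp perfect hairpin planted in an A-background; the site sits on the
  # 5' arm of the stem
  set.seed(53)
  arm <- "GCGCGGCGCCGCGGCCGGCG"
  hairpin <- paste0(arm, "AAAA", revComp(chartr("T", "U", arm)))
  tx <- paste0(strrep("A", 60), hairpin, strrep("A", 60))
  accStem <- accessibility(tx, 61, 80)
  expect_lt(accStem, 0.5)
})

test_that("features ignore transcript sequence beyond the context window", {
  set.seed(59)
  mir <- c(m = randRna(21))
  core <- paste0(randRna(90), revComp(mir[["m"]]), randRna(90))
  ext <- paste0(randRna(40), core, randRna(40))
  sites <- data.frame(mirna_id = "m", transcript_id = "t",
                      site_start = 91L, site_end = 111L)
  sitesExt <- transform(sites, site_start = 131L, site_end = 151L)
  f1 <- featureMatrix(sites, mir, c(t = core))
  f2 <- featureMatrix(sitesExt, mir, c(t = ext))
  expect_equal(f1[, targetFeatureNames()], f2[, targetFeatureNames()])
})

test_that("feature matrices round-trip through CSV", {
  set.seed(61)
  mir <- c(m = randRna(21))
  tx <- c(t = paste0(randRna(30), revComp(mir[["m"]]), randRna(30)))
  fm <- featureMatrix(data.frame(mirna_id = "m", transcript_id = "t",
                                 site_start = 31L, site_end = 51L,
                                 label = "positive"), mir, tx)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeFeatureMatrix(fm, csv)
  back <- readFeatureMatrix(csv)
  expect_equal(back[, targetFeatureNames()], fm[, targetFeatureNames()],
               tolerance = 1e-12)
})
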