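# Synthetic corpus generation: reproducibility, planted-site geometry,
# homolog families, and featurized example assembly.

test_that("corpus specifications are validated", {
  expect_error(corpusSpec(background = "gc_rich"), "background")
  expect_error(corpusSpec(siteStyle = "fungal"), "siteStyle")
  expect_error(corpusSpec(noncanonicalFraction = 1.5), "fractions")
  expect_error(corpusSpec(transcriptLenRange = c(10L, 300L)), "fit")
  expect_output(show(corpusSpec()), "CorpusSpec")
})

test_that("the same spec reproduces the corpus exactly", {
  spec <- corpusSpec(nMirna = 8L, nTranscript = 16L, seed = 7L)
  a <- generateCorpus(spec)
  b <- generateCorpus(spec)
  expect_identical(as.character(a$mirnas), as.character(b$mirnas))
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(a$positives, b$positives)
  c <- generateCorpus(corpusSpec(nMirna = 8L, nTranscript = 16L, seed = 8L))
  expect_false(identical(as.character(a$transcripts),
                         as.character(c$transcripts)))
})

test_that("with zero mutation the planted site is the exact reverse complement", {
  spec <- corpusSpec(nMirna = 6L, nTranscript = 12L, siteMismatchRate = 0,
                     noncanonicalFraction = 0, homologFraction = 0,
                     seed = 11L)
  corpus <- generateCorpus(spec)
  mseq <- as.character(corpus$mirnas)
  tseq <- as.character(corpus$transcripts)
  p <- corpus$positives
  for (i in seq_len(nrow(p))) {
    window <- substr(tseq[[p$transcript_id[i]]], p$site_start[i],
                     p$site_end[i])
    expect_equal(window, revComp(mseq[[p$mirna_id[i]]]))
  }
  expect_true(all(p$site_end - p$site_start + 1 ==
                  nchar(mseq[p$mirna_id])))
  expect_false(any(p$noncanonical))
})

test_that("non-canonical sites carry >= 2 mismatches in the seed-pairing window", {
  spec <- corpusSpec(nMirna = 10L, nTranscript = 40L, siteMismatchRate = 0,
                     noncanonicalFraction = 0.5, homologFraction = 0,
                     seed = 13L)
  corpus <- generateCorpus(spec)
  mseq <- as.character(corpus$mirnas)
  tseq <- as.character(corpus$transcripts)
  p <- corpus$positives
  expect_gt(sum(p$noncanonical), 0)
  for (i in which(p$noncanonical)) {
    m <- mseq[[p$mirna_id[i]]]
    L <- nchar(m)
    site <- substr(tseq[[p$transcript_id[i]]], p$site_start[i], p$site_end[i])
    perfect <- revComp(m)
    seedSitePos <- L - (2:8) + 1
    diffs <- sum(substring(site, seedSitePos, seedSitePos) !=
                 substring(perfect, seedSitePos, seedSitePos))
    expect_gte(diffs, 2)
  }
  # canonical sites with zero mutation rate remain perfect
  for (i in which(!p$noncanonical)) {
    site <- substr(tseq[[p$transcript_id[i]]], p$site_start[i], p$site_end[i])
    expect_equal(site, revComp(mseq[[p$mirna_id[i]]]))
  }
})

test_that("animal-style sites are complementary only opposite miRNA 1-9", {
  spec <- corpusSpec(nMirna = 8L, nTranscript = 24L, siteMismatchRate = 0,
                     homologFraction = 0, background = "au_rich",
                     siteStyle = "animal", speciesLabels = "hsa",
                     seed = 17L)
  corpus <- generateCorpus(spec)
  mseq <- as.character(corpus$mirnas)
  tseq <- as.character(corpus$transcripts)
  p <- corpus$positives
  upstreamMatches <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    m <- mseq[[p$mirna_id[i]]]
    L <- nchar(m)
    site <- substr(tseq[[p$transcript_id[i]]], p$site_start[i], p$site_end[i])
    perfect <- revComp(m)
    # the last 9 site positions face miRNA positions 1-9
    expect_equal(substr(site, L - 8, L), substr(perfect, L - 8, L))
    upstreamMatches[i] <- mean(strsplit(substr(site, 1, L - 9), "")[[1]] ==
                               strsplit(substr(perfect, 1, L - 9), "")[[1]])
  }
  # the 3' region of the site is background, not complementary
  expect_lt(mean(upstreamMatches), 0.6)
})

test_that("homolog families cross species at high identity", {
  spec <- corpusSpec(nMirna = 20L, nTranscript = 20L,
                     homologFraction = 0.3, seed = 19L)
  corpus <- generateCorpus(spec)
  md <- S4Vectors::mcols(corpus$mirnas)
  hom <- which(!is.na(md$homolog_of))
  expect_length(hom, round(0.3 * 20))
  mseq <- as.character(corpus$mirnas)
  for (j in hom) {
    src <- md$homolog_of[j]
    expect_gte(pairwiseIdentity(mseq[[j]], mseq[[src]]), 0.70)
    expect_false(md$species[j] ==
                 md$species[match(src, names(corpus$mirnas))])
  }
})

test_that("corpusToExamples yields labeled, featurized positives and negatives", {
  spec <- corpusSpec(nMirna = 6L, nTranscript = 12L, homologFraction = 0,
                     seed = 23L)
  corpus <- generateCorpus(spec)
  ex <- corpusToExamples(corpus)
  expect_true(all(targetFeatureNames() %in% colnames(ex)))
  expect_true(all(c("mirna_id", "transcript_id", "species", "label",
                    "noncanonical") %in% colnames(ex)))
  expect_equal(sum(ex$label == "positive"), 12L)
  expect_gte(sum(ex$label == "negative"), 10L)
  expect_true(all(is.na(ex$noncanonical[ex$label == "negative"])))
  expect_true(all(ex$species %in% c("gma", "osa")))
  expect_false(anyNA(ex[, targetFeatureNames()]))
  # planted sites score far better than their decoys on pairing features
  expect_gt(mean(ex$n_paired[ex$label == "positive"]),
            mean(ex$n_paired[ex$label == "negative"]) + 5)
})
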