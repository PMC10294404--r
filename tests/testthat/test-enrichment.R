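# Interval-overlap statistics against per-base counting oracles and closed
# forms.

test_that("fold enrichment matches per-base counting on random fixtures", {
  for (i in 1:20) {
    asm <- tinyAssembly(c(chr1 = 1000, chr2 = 995), binSize = 10)
    seg <- randomSegmentation(asm, K = 3, seed = i)
    set.seed(i + 500)
    n <- 30
    chrom <- sample(names(chromSizes(asm)), n, replace = TRUE)
    start <- sample(0:900, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1,
                                                  start + sample(5:80, n, TRUE)))
    et <- foldEnrichment(seg, gr)
    oracle <- oracleFoldEnrichment(seg, gr)
    # exact integer agreement of intersection base counts
    expect_identical(as.numeric(et$intersectionBases[, 1]), oracle$inter)
    expect_equal(as.numeric(et$fold[, 1]), oracle$fold, tolerance = 1e-9)
    # weighted identity: sum_s stateFraction * fold = 1 for the annotation
    expect_equal(sum(et$stateFraction * et$fold[, 1]), 1, tolerance = 1e-6)
  }
})

test_that("hand-sized enrichment example gives fold 5 and percent 50", {
  # 1000-bin genome; state 1 covers bins 1..100; annotation covers bins
  # 1..50 and 501..650 (200 bins, 100 of them in state 1)
  asm <- tinyAssembly(c(chr1 = 10000), binSize = 10)
  states <- rep(2L, 1000)
  states[1:100] <- 1L
  seg <- Segmentation(asm, 2, list(chr1 = states))
  annot <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 5001),
                                                   c(500, 6500)))
  # intersection with state 1 = bins 1..50 = 500 bases of 2000 annotated
  et <- foldEnrichment(seg, annot)
  expect_equal(unname(et$fold[1, 1]), (500 / 10000) / (0.1 * 0.2),
               tolerance = 1e-12)   # = 2.5
  expect_equal(unname(et$percent[1, 1]), 0.25, tolerance = 1e-12)

  # intersection equal to the state's whole territory: percent w.r.t. an
  # annotation identical to the state is 100%
  own <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  et2 <- foldEnrichment(seg, own)
  expect_equal(unname(et2$percent[1, 1]), 1, tolerance = 1e-12)
})

test_that("a state covering the whole genome has fold 1 everywhere", {
  asm <- tinyAssembly(c(chr1 = 1000), binSize = 10)
  seg <- Segmentation(asm, 1, list(chr1 = rep(1L, 100)))
  annot <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 300))
  expect_equal(unname(foldEnrichment(seg, annot)$fold[1, 1]), 1,
               tolerance = 1e-12)
  # empty annotation reported missing
  empty <- GenomicRanges::GRanges()
  expect_true(is.na(foldEnrichment(seg, empty)$fold[1, 1]))
})

test_that("Jaccard arithmetic matches closed forms and set identities", {
  res <- jaccardIndex(413502000, 238977200, 193765600)
  expect_identical(res$union, 458713600)
  expect_equal(round(res$jaccard, 2), 0.42)

  A <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), c(50, 200)))
  self <- jaccardSets(A, A)
  expect_equal(self$jaccard, 1)
  B <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 400))
  expect_equal(jaccardSets(A, B)$jaccard, 0)
  expect_error(jaccardIndex(10, 10, 11), "exceed")
})

test_that("positional profiles find a state planted downstream of anchors", {
  asm <- tinyAssembly(c(chr1 = 4000), binSize = 10)
  n <- 400
  states <- rep(1L, n)
  # anchors at bins 50, 150, 250 (+ strand) and 350 (- strand);
  # state 2 planted exactly 2 bins downstream of each anchor
  plusBins <- c(50, 150, 250)
  minusBin <- 350
  states[plusBins + 2] <- 2L
  states[minusBin - 2] <- 2L
  seg <- Segmentation(asm, 2, list(chr1 = states))
  anchors <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(plusBins, minusBin) * 10 - 9, width = 1),
    strand = c("+", "+", "+", "-"))
  prof <- positionalEnrichment(seg, anchors, windowBins = 5)
  peak <- which.max(prof$fold[2, ])
  expect_identical(prof$offsets[peak], 20)  # +2 bins in transcription sense
  expect_equal(unname(prof$fold[2, "20"]),
               1 / (sum(states == 2L) / n), tolerance = 1e-9)

  # single-state segmentation: profile identically 1
  seg1 <- Segmentation(asm, 1, list(chr1 = rep(1L, n)))
  prof1 <- positionalEnrichment(seg1, anchors, windowBins = 3)
  expect_true(all(prof1$fold == 1))

  expect_error(positionalEnrichment(seg, GenomicRanges::GRanges()), "empty")
})

test_that("geometric summaries follow the zero-replacement rule", {
  expect_equal(groupedGeometricSummary(c(4, 1))$geoMean, 2, tolerance = 1e-12)
  # zeros replaced by the minimum non-zero value (3): (3*9*3)^(1/3)
  expect_equal(groupedGeometricSummary(c(0, 9, 3))$geoMean, 4.326749,
               tolerance = 1e-6)
  res <- groupedGeometricSummary(c(5, 5, 5))
  expect_equal(res$geoMean, 5)
  expect_equal(res$geoSD, 1)
  expect_true(is.na(groupedGeometricSummary(c(0, 0))$geoMean))
  # scale equivariance
  x <- c(0, 2, 8, 1)
  a <- groupedGeometricSummary(x)
  b <- groupedGeometricSummary(x * 7)
  expect_equal(b$geoMean, a$geoMean * 7, tolerance = 1e-12)
  expect_equal(b$geoSD, a$geoSD, tolerance = 1e-12)
})

test_that("chromosome enrichment recovers confinement and the weighted identity", {
  asm1 <- tinyAssembly(c(chr1 = 1000), binSize = 10)
  seg1 <- randomSegmentation(asm1, K = 3, seed = 2)
  et1 <- chromosomeEnrichment(seg1)
  present <- et1$stateFraction > 0
  expect_equal(unname(et1$fold[present, 1]), rep(1, sum(present)),
               tolerance = 1e-12)

  asm2 <- tinyAssembly(c(chr1 = 1000, chr2 = 1000), binSize = 10)
  states <- list(chr1 = rep(2L, 100), chr2 = rep(1L, 100))
  seg2 <- Segmentation(asm2, 2, states)
  et2 <- chromosomeEnrichment(seg2)
  expect_equal(unname(et2$fold[1, "chr2"]), 2, tolerance = 1e-12)
  expect_equal(unname(et2$fold[1, "chr1"]), 0, tolerance = 1e-12)
  for (a in colnames(et2$fold))
    expect_equal(sum(et2$stateFraction * et2$fold[, a]), 1, tolerance = 1e-6)
})

test_that("per-cell-type summaries reduce to identity on identical annotations", {
  asm <- tinyAssembly(c(chr1 = 1000), binSize = 10)
  seg <- randomSegmentation(asm, K = 4, seed = 3)
  res <- perCellTypeSummary(seg, list(e1 = seg, e2 = seg),
                            c(e1 = "gA", e2 = "gA"))
  expect_identical(unname(res$maxEnriched[, "e1"]), 1:4)
  pm <- res$groupProbs$gA
  expect_equal(unname(pm[, 1:4]), diag(4), tolerance = 1e-12)
  expect_equal(unname(rowSums(pm)), rep(1, 4), tolerance = 1e-6)
})

test_that("group overlap probabilities average per-epigenome fractions", {
  asm <- tinyAssembly(c(chr1 = 40), binSize = 10)
  full <- Segmentation(asm, 2, list(chr1 = c(1L, 1L, 2L, 2L)))
  e1 <- Segmentation(asm, 2, list(chr1 = c(1L, 2L, 2L, 2L)))
  e2 <- Segmentation(asm, 2, list(chr1 = c(1L, 1L, 1L, 2L)))
  res <- perCellTypeSummary(full, list(e1 = e1, e2 = e2),
                            c(e1 = "g", e2 = "g"))
  # state 1 of the joint annotation: e1 splits its bases 1/2 - 1/2,
  # e2 gives 1 - 0; the group average is (0.5+1)/2 and (0.5+0)/2
  expect_equal(unname(res$groupProbs$g[1, ]), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(unname(res$groupProbs$g[2, ]), c(0.25, 0.75), tolerance = 1e-12)

  asm2 <- tinyAssembly(c(chr1 = 40, chr2 = 40), binSize = 10)
  full2 <- randomSegmentation(asm2, K = 2, seed = 4)
  expect_error(perCellTypeSummary(full2, list(e1 = e1), c(e1 = "g")), "chr2")
})

test_that("score averages are base-weighted and missing-aware", {
  asm <- tinyAssembly(c(chr1 = 95), binSize = 10)  # terminal partial bin
  seg <- Segmentation(asm, 3, list(chr1 = c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 2L, 2L)))
  sc <- list(chr1 = c(0.2, 0.2, 0.8, 0.8, 0.8, 0.2, 0.2, 0.2, 0.8, 0.8))
  av <- scoreAverage(seg, sc)
  expect_equal(unname(av[1]), 0.2, tolerance = 1e-12)
  expect_equal(unname(av[2]), 0.8, tolerance = 1e-12)
  expect_true(is.na(av[3]))  # state 3 has no bases at all
  # constant track: every state averages the constant
  const <- list(chr1 = rep(0.4, 10))
  expect_equal(unname(scoreAverage(seg, const)[1:2]), c(0.4, 0.4),
               tolerance = 1e-12)
  # unscored bins drop out of numerator and denominator
  sc2 <- sc
  sc2$chr1[1:2] <- NA
  expect_equal(unname(scoreAverage(seg, sc2)[1]), 0.2, tolerance = 1e-12)
})

test_that("rank correlation reproduces the average-rank convention", {
  set.seed(15)
  for (i in 1:10) {
    x <- sample(1:5, 6, replace = TRUE)  # ties likely
    y <- rnorm(6)
    expect_equal(spearmanRank(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  # exhaustive check over all permutations of a small vector
  y <- c(2, 4, 1, 3)
  perms <- ChromStack:::.permutations(4)
  for (r in seq_len(nrow(perms))) {
    x <- perms[r, ]
    expect_equal(spearmanRank(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("planted annotations come back at the configured fold", {
  asm <- GenomeAssembly("toy", c(chr1 = 4e6), 200)  # 20,000 bins
  model <- genModel(4, marks = c("m1", "m2"), cellGroups = "g1", seed = 16)
  sim <- simulateTracks(model, asm, 0, seed = 16)
  seg <- Segmentation(asm, 4, sim$truePath)
  frac <- mean(sim$truePath$chr1 == 2)
  fold <- min(3, 0.9 / frac)
  gr <- genPlantedAnnotation(asm, sim$truePath, state = 2, fold = fold,
                             nIntervals = 500, seed = 16)
  est <- unname(foldEnrichment(seg, gr)$fold[2, 1])
  # binomial CI half-width on the in-state proportion at n = 500
  q <- fold * frac
  halfWidth <- 3 * sqrt(q * (1 - q) / 500) / frac
  expect_lt(abs(est - fold), halfWidth)
})
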