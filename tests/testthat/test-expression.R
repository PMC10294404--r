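# Gene-length-normalized state expression and segment-mapping transfer.

test_that("the expression transform is log2(FPKM + 1)", {
  expect_equal(transformExpression(0), 0)
  expect_equal(transformExpression(1), 1)
  expect_equal(transformExpression(3), 2)
  expect_error(transformExpression(-1), "non-negative")
})

test_that("the printed two-gene example evaluates to 8/3", {
  asm <- GenomeAssembly("toy", c(chr1 = 600), 200)
  seg <- Segmentation(asm, 2, list(chr1 = c(1L, 2L, 2L)))
  # both genes overlap bin 1 only; state 1 = that single bin
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "+"), tss = c(0, 50), tes = c(150, 180),
                      exon_starts = c("0", "50"), exon_ends = c("150", "180"),
                      length = c(1000, 2000), stringsAsFactors = FALSE)
  expression <- c(g1 = 2, g2 = 4)
  avg <- stateAvgExpression(seg, genes, expression)
  expect_equal(unname(avg[1]), (2 / 1000 + 4 / 2000) / (1 / 1000 + 1 / 2000),
               tolerance = 1e-12)   # 8/3
  expect_equal(unname(avg[1]), 8 / 3, tolerance = 1e-12)
  expect_true(is.na(avg[2]))  # no gene overlaps state 2
})

test_that("a single gene spanning one state returns its own expression", {
  asm <- GenomeAssembly("toy", c(chr1 = 2000), 200)
  seg <- Segmentation(asm, 2, list(chr1 = c(rep(1L, 5), rep(2L, 5))))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 0, tes = 1000, exon_starts = "0",
                      exon_ends = "1000", length = 1000,
                      stringsAsFactors = FALSE)
  avg <- stateAvgExpression(seg, genes, c(g1 = 8))
  expect_equal(unname(avg[1]), 8, tolerance = 1e-12)  # weights cancel
})

test_that("state expression equals the naive triple-loop oracle", {
  for (i in 1:5) {
    asm <- tinyAssembly(c(chr1 = 1500, chr2 = 500), binSize = 10)  # 200 bins
    seg <- randomSegmentation(asm, K = 3, seed = i)
    set.seed(i + 300)
    n <- 25
    chrom <- sample(names(chromSizes(asm)), n, replace = TRUE)
    start <- vapply(chrom, function(ch) sample(0:(chromSizes(asm)[[ch]] - 60), 1),
                    numeric(1))
    len <- sample(20:300, n, replace = TRUE)
    end <- pmin(start + len, chromSizes(asm)[chrom])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("g%d", seq_len(n)), chrom = chrom,
                        strand = strand,
                        tss = ifelse(strand == "+", start, end),
                        tes = ifelse(strand == "+", end, start),
                        exon_starts = as.character(start),
                        exon_ends = as.character(end),
                        length = end - start, stringsAsFactors = FALSE)
    expression <- setNames(round(runif(n, 0, 10), 3), genes$gene_id)
    avg <- stateAvgExpression(seg, genes, expression)
    oracle <- oracleStateExpression(seg, genes, expression)
    expect_equal(unname(avg), oracle, tolerance = 1e-12)
    # bounded by the contributing genes
    ok <- !is.na(avg)
    expect_true(all(avg[ok] >= min(expression) - 1e-12))
    expect_true(all(avg[ok] <= max(expression) + 1e-12))
  }
})

test_that("splitting a gene record leaves the state averages unchanged", {
  asm <- tinyAssembly(c(chr1 = 1000), binSize = 10)
  seg <- randomSegmentation(asm, K = 2, seed = 9)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", tss = c(100, 500), tes = c(300, 900),
                      exon_starts = c("100", "500"), exon_ends = c("300", "900"),
                      length = c(200, 400), stringsAsFactors = FALSE)
  expression <- c(g1 = 3, g2 = 7)
  a <- stateAvgExpression(seg, genes, expression)
  # replicate g2 as two records with identical E and L covering the same span
  split <- rbind(genes[1, ],
                 transform(genes[2, ], gene_id = "g2a", tes = 700),
                 transform(genes[2, ], gene_id = "g2b", tss = 700))
  exprSplit <- c(g1 = 3, g2a = 7, g2b = 7)
  b <- stateAvgExpression(seg, split, exprSplit)
  # overlap bookkeeping: the two halves tile the original body, so every
  # bin still sees one record with the same E and L (split at a bin edge)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("replicate averaging honors tissues and missing values", {
  mat <- matrix(c(2, 4, 4, 8, 1, NA), nrow = 1,
                dimnames = list("E1", c("a_rep1", "a_rep2", "b_rep1",
                                        "b_rep2", "c_rep1", "c_rep2")))
  tissueOf <- c(a_rep1 = "a", a_rep2 = "a", b_rep1 = "b", b_rep2 = "b",
                c_rep1 = "c", c_rep2 = "c")
  expect_warning(avg <- replicateTissueAverage(mat, tissueOf),
                 "only one replicate")
  expect_equal(unname(avg[1, ]), c(3, 6, 1))
  # identical replicates pass through unchanged and shape is states x tissues
  mat19 <- matrix(5, 2, 38,
                  dimnames = list(NULL, paste0("t", rep(1:19, each = 2),
                                               "_rep", 1:2)))
  t19 <- setNames(paste0("t", rep(1:19, each = 2)), colnames(mat19))
  avg19 <- replicateTissueAverage(mat19, t19)
  expect_identical(dim(avg19), c(2L, 19L))
  expect_true(all(avg19 == 5))
})

test_that("segment mapping transfers states and drops collided destinations", {
  asm <- tinyAssembly(c(chr1 = 2000), binSize = 200)
  seg <- Segmentation(asm, 3, list(chr1 = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L, 1L)))
  ident <- genMapping(asm, asm, 0, 0, seed = 1)
  mapped <- applySegmentMapping(seg, ident, asm)
  expect_identical(stateSeqs(mapped)$chr1, stateSeqs(seg)$chr1)
  expect_identical(attr(mapped, "excludedBins"), 0L)

  # redirect segment 2 onto destination bin 5: bin 5 now has two sources
  collided <- ident
  collided$dst_start[2] <- 800
  collided$dst_end[2] <- 1000
  mapped2 <- applySegmentMapping(seg, collided, asm)
  expect_true(is.na(stateSeqs(mapped2)$chr1[5]))
  expect_true(is.na(stateSeqs(mapped2)$chr1[2]))  # nothing maps there now
  expect_identical(attr(mapped2, "excludedBins"), 1L)

  # generated multimap fixture: exclusion count equals the collision oracle
  asm2 <- tinyAssembly(c(chr1 = 40000, chr2 = 40000), binSize = 200)
  seg2 <- randomSegmentation(asm2, K = 4, seed = 2)
  mp <- genMapping(asm2, asm2, multimapRate = 0.05, dropRate = 0.05, seed = 2)
  mapped3 <- applySegmentMapping(seg2, mp, asm2)
  expect_identical(attr(mapped3, "excludedBins"),
                   as.integer(oracleCollisionBins(mp, 200)))
  # uniquely mapped bins carry a state, everything else is NA
  assigned <- sum(!is.na(unlist(stateSeqs(mapped3))))
  key <- paste(mp$dst_chrom, mp$dst_start %/% 200)
  expect_identical(assigned, as.integer(sum(table(key) == 1)))
})
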