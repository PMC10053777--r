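# MDS outlier screen, common-dispersion estimation, the NB Wald contrast
# and DEG classification.

makeSim <- function(nGenes = 800, ..., seed = 1, samplesPerGroup = 3) {
  simulateCounts(synthTruth(nGenes, seed = seed, ...),
                 samplesPerGroup = samplesPerGroup)
}

test_that("median-of-ratios size factors recover known scalings", {
  sim <- makeSim(500, deFraction = 0, seed = 21)
  cts <- counts(sim$counts)
  scaled <- cts
  scaled[, 1] <- scaled[, 1] * 4L
  sf <- estimateSizeFactors(scaled)
  sf0 <- estimateSizeFactors(cts)
  # size-factor ratios are the identified quantity: scaling one sample by
  # 4 multiplies its ratio to every other sample by 4
  expect_equal(unname(sf[1] / sf[-1]), unname(4 * sf0[1] / sf0[-1]),
               tolerance = 1e-10)
  expect_equal(unname(sf[2] / sf[-(1:2)]), unname(sf0[2] / sf0[-(1:2)]),
               tolerance = 1e-10)
})

test_that("identical samples yield zero MDS spread and no outliers", {
  one <- matrix(rpois(200, 20), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  one[, 2] <- one[, 1]; one[, 3] <- one[, 1]; one[, 4] <- one[, 1]
  scr <- mdsScreen(MixtureExperiment(one, rep(c("a", "b"), each = 2)))
  expect_true(all(scr$dist_to_centroid == 0))
  expect_false(any(scr$outlier_flag))
})

test_that("a gene-permuted replicate is flagged as an MDS outlier", {
  sim <- makeSim(2000, seed = 23)
  cts <- counts(sim$counts)
  set.seed(1)
  cts[, 2] <- cts[sample(nrow(cts)), 2]
  scr <- mdsScreen(MixtureExperiment(cts,
                                     as.character(sampleGroups(sim$counts))))
  expect_true(scr$outlier_flag[2])
  # the permuted sample is the most extreme; clean groups stay unflagged
  expect_equal(which.max(scr$dist_to_centroid), 2L)
  expect_false(any(scr$outlier_flag[scr$group != "control"]))
})

test_that("MDS screen validates its input dimensions", {
  m <- matrix(rpois(20, 10), 10, 2,
              dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  expect_error(mdsScreen(m, group = c("a", "b")), "3 samples")
})

test_that("common dispersion hits the Poisson limit and needs replication", {
  sim <- makeSim(5000, deFraction = 0, alpha = 0, seed = 31)
  expect_lt(estimateCommonDispersion(sim$counts), 0.01)

  m <- matrix(rpois(40, 10), 20, 2,
              dimnames = list(paste0("g", 1:20), c("s1", "s2")))
  expect_error(estimateCommonDispersion(m, group = c("a", "b")),
               "not estimable")
})

test_that("the Wald contrast recovers planted effects", {
  tr <- synthTruth(2000, deFraction = 0.1, thetaRange = c(2, 2),
                   epsSd = 0, alpha = 0.05, baseMean = 200, seed = 3)
  sim <- simulateCounts(tr, samplesPerGroup = 4)
  ah <- estimateCommonDispersion(sim$counts)
  cc <- as.data.frame(nbWaldContrast(sim$counts, "mixtureA", "control", ah))
  planted <- names(tr@theta)[tr@theta != 0]
  est <- cc$log2FC[match(planted, cc$gene_id)] * sign(tr@theta[planted])
  expect_gte(median(est), 1.8)
  expect_lte(median(est), 2.2)
})

test_that("an identical treatment gives zero log2FC and p of one", {
  sim <- makeSim(300, deFraction = 0, seed = 41)
  cts <- counts(sim$counts)[, 1:6]
  cts[, 4:6] <- cts[, 1:3]  # treatment duplicates control sample-for-sample
  colnames(cts) <- paste0("s", 1:6)
  cc <- as.data.frame(nbWaldContrast(cts, "t", "c", alpha = 0.05,
                                     group = rep(c("c", "t"), each = 3)))
  ok <- !is.na(cc$p)
  expect_true(all(abs(cc$log2FC[ok]) < 1e-6))
  expect_true(all(cc$p[ok] > 1 - 1e-6))
})

test_that("swapping treatment and control negates log2FC, keeps p", {
  sim <- makeSim(400, seed = 43)
  ah <- estimateCommonDispersion(sim$counts)
  a <- as.data.frame(nbWaldContrast(sim$counts, "mixtureA", "control", ah))
  b <- as.data.frame(nbWaldContrast(sim$counts, "control", "mixtureA", ah))
  ok <- !is.na(a$p)
  expect_equal(a$log2FC[ok], -b$log2FC[ok], tolerance = 1e-8)
  expect_equal(a$p[ok], b$p[ok], tolerance = 1e-8)
})

test_that("doubling all counts leaves log2FC unchanged", {
  sim <- makeSim(300, seed = 47)
  ah <- 0.05
  grp <- as.character(sampleGroups(sim$counts))
  sf <- rep(1, length(grp))
  a <- as.data.frame(nbWaldContrast(counts(sim$counts), "mixtureA",
                                    "control", ah, group = grp,
                                    sizeFactors = sf))
  doubled <- counts(sim$counts) * 2L
  b <- as.data.frame(nbWaldContrast(doubled, "mixtureA", "control", ah,
                                    group = grp, sizeFactors = 2 * sf))
  ok <- !is.na(a$log2FC) & !is.na(b$log2FC)
  expect_equal(a$log2FC[ok], b$log2FC[ok], tolerance = 1e-6)
})

test_that("all-zero genes are excluded from the BH family", {
  sim <- makeSim(200, deFraction = 0, seed = 51)
  cts <- counts(sim$counts)[, 1:6]
  cts[1:5, ] <- 0L
  cc <- as.data.frame(nbWaldContrast(cts, "mixtureA", "control", 0.05,
                                     group = rep(c("control", "mixtureA"),
                                                 each = 3)))
  zeroed <- cc$gene_id %in% rownames(cts)[1:5]
  expect_true(all(is.na(cc$p[zeroed])))
  expect_true(all(is.na(cc$p_adj[zeroed])))
  # BH computed over the tested genes only, and monotone with p
  tested <- cc[!is.na(cc$p), ]
  expect_equal(tested$p_adj, p.adjust(tested$p, "BH"))
  expect_identical(order(tested$p), order(tested$p_adj, tested$p))
})

test_that("DEG classification applies both thresholds and direction", {
  toy <- toyContrast(lfc = c(1.5, 0.9, 1.5), padj = c(0.01, 0.01, 0.2))
  d <- classifyDegs(toy, lfcMin = 1, padjMax = 0.05)
  expect_identical(degGenes(d), "g001")
  expect_identical(unname(d@direction), 1)

  all <- classifyDegs(toy, lfcMin = 0, padjMax = 1)
  expect_identical(degGenes(all), toy$gene_id)

  down <- classifyDegs(toyContrast(-2, 0.001), lfcMin = 1, padjMax = 0.05)
  expect_identical(unname(down@direction), -1)
})

test_that("contrast TSVs round-trip", {
  sim <- makeSim(100, seed = 61)
  cc <- nbWaldContrast(sim$counts, "mixtureA", "control", 0.05)
  f <- tempfile(fileext = ".tsv")
  writeContrastTsv(cc, f)
  back <- readContrastTsv(f, "mixtureA", "control")
  expect_equal(as.data.frame(back)$log2FC, as.data.frame(cc)$log2FC,
               tolerance = 1e-12)
})

test_that("null raw p-values are uniform", {
  sim <- makeSim(5000, deFraction = 0, epsSd = 0, alpha = 0.05, seed = 71)
  ah <- estimateCommonDispersion(sim$counts)
  cc <- as.data.frame(nbWaldContrast(sim$counts, "mixtureB", "control", ah))
  p <- cc$p[!is.na(cc$p)]
  expect_gt(length(p), 4900)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("dispersion and contrasts agree with independent implementations", {
  skip_if_not_installed("edgeR")
  skip_if_not_installed("DESeq2")
  sim <- makeSim(800, seed = 73)
  grp <- as.character(sampleGroups(sim$counts))
  ah <- estimateCommonDispersion(sim$counts)

  # edgeR's Cox-Reid common dispersion as an independent estimator
  design <- stats::model.matrix(~grp)
  d <- edgeR::DGEList(counts = counts(sim$counts), group = grp)
  d <- edgeR::normLibSizes(d)
  d <- edgeR::estimateGLMCommonDisp(d, design)
  expect_lt(abs(ah - d$common.dispersion), 0.02)

  # DESeq2 Wald fit at the same fixed dispersion
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts(sim$counts), data.frame(condition = factor(grp)), ~condition)
    dds <- DESeq2::estimateSizeFactors(dds)
    DESeq2::dispersions(dds) <- rep(ah, nrow(dds))
    dds <- DESeq2::nbinomWaldTest(dds)
    res <- DESeq2::results(dds,
                           contrast = c("condition", "mixtureA", "control"))
  })
  mine <- as.data.frame(nbWaldContrast(sim$counts, "mixtureA", "control",
                                       ah))
  theirs <- res$log2FoldChange[match(mine$gene_id, rownames(res))]
  ok <- is.finite(mine$log2FC) & is.finite(theirs) &
    abs(mine$log2FC) < 10  # exclude one-group-zero pseudo-count genes
  expect_gt(cor(mine$log2FC[ok], theirs[ok]), 0.99)
  expect_lt(median(abs(mine$log2FC[ok] - theirs[ok])), 0.05)
})
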