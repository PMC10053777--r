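# Overlap coefficients, Jaccard distances, enrichment-map components and
# the Jaccard-merge term reduction.

enrichRowsFor <- function(col, queryId = "q", ratio = NULL, padj = NULL) {
  n <- length(col)
  data.frame(term_id = names(col), term_name = col@termName,
             query_id = queryId, namespace = col@namespace,
             k = 5L, n = 10L, K = lengths(col@genes),
             N = max(lengths(col@genes)) * 10L,
             p = 1e-4, p_adj = padj %||% rep(1e-3, n),
             ratio = ratio %||% rep(5, n), significant = TRUE)
}

test_that("overlap coefficient and Jaccard distance match set arithmetic", {
  expect_equal(overlapCoefficient(letters[1:4], letters[1:4]), 1)
  expect_equal(overlapCoefficient(letters[1:3], letters[10:12]), 0)
  expect_equal(overlapCoefficient(c("a", "b", "c", "d"), c("c", "d", "e")),
               2 / 3)
  expect_error(overlapCoefficient(character(), "a"), "non-empty")

  expect_equal(jaccardDistance(letters[1:5], letters[1:5]), 0)
  expect_equal(jaccardDistance(letters[1:3], letters[10:12]), 1)
  expect_equal(jaccardDistance(as.character(1:10), as.character(1:6)), 0.4)
  expect_error(jaccardDistance(character(), character()), "empty")
})

test_that("both statistics hit 1/0 together exactly for equal-size sets", {
  set.seed(19)
  for (i in 1:200) {
    u <- sprintf("x%03d", 1:40)
    a <- sample(u, 12); b <- sample(u, 12)
    oc <- overlapCoefficient(a, b); jd <- jaccardDistance(a, b)
    expect_identical(oc == 1, setequal(a, b))
    expect_identical(jd == 0, setequal(a, b))
  }
})

test_that("nested terms form one fully connected cluster", {
  u <- sprintf("g%03d", 1:100)
  col <- makeCollection(c("T1", "T2", "T3"),
                        list(u[1:10], u[1:25], u[1:60]))
  tg <- buildEnrichmentMap(enrichRowsFor(col), col, threshold = 0.4)
  expect_equal(nrow(tg@edges), 3)
  expect_true(all(tg@edges$coefficient == 1))
  expect_equal(length(unique(tg@nodes$cluster)), 1)
})

test_that("below-threshold graphs fall apart into singletons", {
  u <- sprintf("g%03d", 1:90)
  col <- makeCollection(paste0("T", 1:3),
                        list(u[1:30], u[31:60], u[61:90]))
  tg <- buildEnrichmentMap(enrichRowsFor(col), col, threshold = 0.4)
  expect_equal(nrow(tg@edges), 0)
  expect_equal(length(unique(tg@nodes$cluster)), 3)
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(23)
  u <- sprintf("g%04d", 1:600)
  for (rep in 1:20) {
    sets <- lapply(1:50, function(i) sample(u, sample(10:40, 1)))
    col <- makeCollection(sprintf("T%02d", 1:50), sets)
    tg <- buildEnrichmentMap(enrichRowsFor(col), col, threshold = 0.4)
    oracle <- unionFindComponents(tg@nodes$node_id,
                                  tg@edges$source, tg@edges$target)
    expect_true(samePartition(tg@nodes$cluster,
                              oracle[tg@nodes$node_id]))
    # every reported edge really clears the threshold, no self-loops
    if (nrow(tg@edges)) {
      expect_true(all(tg@edges$coefficient >= 0.4))
      expect_false(any(tg@edges$source == tg@edges$target))
    }
  }
})

test_that("raising the edge threshold never merges components", {
  set.seed(29)
  u <- sprintf("g%04d", 1:400)
  sets <- lapply(1:30, function(i) sample(u, sample(10:50, 1)))
  col <- makeCollection(sprintf("T%02d", 1:30), sets)
  rows <- enrichRowsFor(col)
  nComp <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    length(unique(buildEnrichmentMap(rows, col,
                                     threshold = th)@nodes$cluster)))
  expect_true(all(diff(nComp) >= 0))
})

test_that("clusters of more than three terms are flagged for annotation", {
  u <- sprintf("g%03d", 1:200)
  col <- makeCollection(paste0("T", 1:5),
                        c(lapply(0:3, function(i) u[(1 + 5 * i):(40 + 5 * i)]),
                          list(u[150:190])))
  tg <- buildEnrichmentMap(enrichRowsFor(col), col, threshold = 0.4)
  big <- names(which(table(tg@nodes$cluster) > 3))
  expect_true(all(tg@nodes$flagged[tg@nodes$cluster %in% big]))
  expect_false(any(tg@nodes$flagged[!tg@nodes$cluster %in% big]))
  annotateCluster(tg) <- setNames("xenobiotic response", big[1])
  expect_identical(unname(tg@annotations[big[1]]), "xenobiotic response")
})

test_that("duplicate terms merge under the smallest-name rule", {
  u <- sprintf("g%03d", 1:100)
  col <- makeCollection(c("TB", "TA"), list(u[1:20], u[1:20]))
  red <- reduceTerms(enrichRowsFor(col), col, topN = 60, mergeAt = 0.45)
  expect_equal(unique(red@summary$merged_term), "TA")  # tie -> lexicographic
  expect_setequal(red@manifest$constituent, c("TA", "TB"))

  # smallest in-universe term donates its name
  col2 <- makeCollection(c("TA", "TB"), list(u[1:20], u[1:18]))
  red2 <- reduceTerms(enrichRowsFor(col2), col2, topN = 60, mergeAt = 0.45)
  expect_equal(unique(red2@summary$merged_term), "TB")
})

test_that("distant terms are never merged", {
  u <- sprintf("g%03d", 1:200)
  col <- makeCollection(paste0("T", 1:4),
                        lapply(0:3, function(i) u[(1 + 50 * i):(50 * i + 40)]))
  red <- reduceTerms(enrichRowsFor(col), col, topN = 60, mergeAt = 0.45)
  expect_equal(sort(unique(red@summary$merged_term)), paste0("T", 1:4))
  expect_equal(nrow(red@manifest), 4)
})

test_that("planted near-duplicate families reduce to one row each", {
  set.seed(37)
  u <- sprintf("g%04d", 1:2000)
  fams <- lapply(0:3, function(f) u[(1 + 300 * f):(300 * f + 60)])
  sets <- list(); ids <- character()
  for (f in 1:4) for (v in 1:5) {
    core <- fams[[f]]
    # within-family Jaccard < 0.2, between-family = 1 (disjoint cores)
    sets[[length(sets) + 1]] <- sample(core, 55)
    ids <- c(ids, sprintf("F%d_%d", f, v))
  }
  col <- makeCollection(ids, sets)
  red <- reduceTerms(enrichRowsFor(col), col, topN = 60, mergeAt = 0.45)
  expect_equal(length(unique(red@summary$merged_term)), 4)
  # membership matches the construction
  fam <- sub("_.*", "", red@manifest$constituent)
  expect_equal(length(unique(paste(red@manifest$merged_term, fam))), 4)
  # merged constituents sit within the merge radius (complete linkage)
  for (mt in unique(red@manifest$merged_term)) {
    cs <- red@manifest$constituent[red@manifest$merged_term == mt]
    gs <- geneSets(col)[cs]
    for (i in seq_along(cs)) for (j in seq_len(i - 1))
      expect_lt(jaccardDistance(gs[[i]], gs[[j]]), 0.45)
  }
})

test_that("term reduction ignores input row order", {
  set.seed(41)
  u <- sprintf("g%03d", 1:500)
  sets <- lapply(1:12, function(i) sample(u, 30))
  col <- makeCollection(sprintf("T%02d", 1:12), sets)
  rows <- enrichRowsFor(col, ratio = runif(12, 2, 8))
  r1 <- reduceTerms(rows, col)
  r2 <- reduceTerms(rows[sample(nrow(rows)), ], col)
  o <- function(d) d[order(d$merged_term, d$treatment), ]
  expect_equal(o(r1@summary), o(r2@summary), ignore_attr = TRUE)
  expect_equal(nrow(reduceTerms(rows[0, ], col)@summary), 0)
})

test_that("per-treatment top-N keeps the highest enrichment ratios", {
  u <- sprintf("g%03d", 1:900)
  sets <- lapply(0:8, function(i) u[(1 + 100 * i):(100 * i + 40)])
  col <- makeCollection(paste0("T", 1:9), sets)
  rows <- enrichRowsFor(col, ratio = 9:1)
  red <- reduceTerms(rows, col, topN = 3, mergeAt = 0.45)
  expect_setequal(unique(red@summary$merged_term), paste0("T", 1:3))
})

test_that("cluster fold-change summaries equal direct recomputation", {
  u <- sprintf("g%03d", 1:60)
  col <- makeCollection(c("T1", "T2"), list(u[1:20], u[15:40]))
  rows <- enrichRowsFor(col)
  tg <- buildEnrichmentMap(rows, col, threshold = 0.2)
  cid <- tg@nodes$cluster[1]
  lfc <- setNames(c(rep(-0.5, 30), rep(1, 30)), u)
  contrast <- data.frame(gene_id = u, log2FC = unname(lfc),
                         wald_stat = NA, p = 0.01, p_adj = 0.01)
  res <- clusterMeanLfc(tg, cid, col, contrast)
  terms <- unique(tg@nodes$term_id[tg@nodes$cluster == cid])
  genes <- unique(unlist(geneSets(col)[terms]))
  expect_equal(res$n_genes, length(genes))
  expect_equal(res$mean_lfc, mean(lfc[genes]))
  expect_equal(res$mean_abs_lfc, mean(abs(lfc[genes])))
  expect_equal(res$frac_down, mean(lfc[genes] < 0))

  # constant-value cases
  c2 <- data.frame(gene_id = u, log2FC = -0.5, wald_stat = NA,
                   p = 0.01, p_adj = 0.01)
  r2 <- clusterMeanLfc(tg, cid, col, c2)
  expect_equal(r2$mean_lfc, -0.5)
  expect_equal(r2$frac_down, 1)

  # empty intersection reports empty, not an error
  r3 <- clusterMeanLfc(tg, cid, col, contrast, degs = "not_a_gene")
  expect_equal(r3$n_genes, 0L)
  expect_true(is.na(r3$mean_lfc))
})

test_that("term graphs serialize to GraphML and TSV", {
  u <- sprintf("g%03d", 1:50)
  col <- makeCollection(c("T1", "T2"), list(u[1:20], u[10:30]))
  tg <- buildEnrichmentMap(enrichRowsFor(col), col, threshold = 0.2)
  pre <- tempfile()
  paths <- writeTermGraph(tg, pre)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[2])
  expect_equal(nrow(edges), nrow(tg@edges))
})
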