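# Three-way DEG partition, term-size filtering, the hypergeometric
# overrepresentation test and GMT round-tripping.

test_that("the DEG partition is a disjoint three-way split", {
  p <- partitionDegs(c("1", "2", "3"), c("3", "4"))
  expect_identical(p, list(A_only = c("1", "2"), overlap = "3",
                           B_only = "4"))
  pSame <- partitionDegs(c("a", "b"), c("a", "b"))
  expect_identical(pSame$overlap, c("a", "b"))
  expect_length(pSame$A_only, 0)

  set.seed(14)
  for (i in 1:200) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    p <- partitionDegs(a, b)
    expect_equal(length(p$A_only) + length(p$overlap) + length(p$B_only),
                 length(union(a, b)))
    expect_length(intersect(p$A_only, p$B_only), 0)
    expect_length(intersect(p$A_only, p$overlap), 0)
    for (g in union(a, b)) {
      where <- c(g %in% p$A_only, g %in% p$overlap, g %in% p$B_only)
      expect_equal(sum(where), 1)
      expect_identical(which(where),
                       which(c(g %in% a && !g %in% b,
                               g %in% a && g %in% b,
                               !g %in% a && g %in% b)))
    }
  }
})

test_that("term-size filtering uses inclusive in-universe bounds", {
  u <- sprintf("u%03d", 1:500)
  sizes <- c(14, 15, 400, 401)
  col <- makeCollection(paste0("T", sizes),
                        lapply(sizes, function(s) u[seq_len(s)]))
  kept <- filterTerms(col, 15, 400, u)
  expect_setequal(names(kept), c("T15", "T400"))

  # out-of-universe members don't count toward the size
  col2 <- makeCollection("X", list(c(u[1:14], "nonexistent_gene")))
  expect_length(filterTerms(col2, 15, 400, u), 0)
  expect_error(filterTerms(col, 30, 20, u), "minSize")
})

test_that("random collections filter identically to direct enumeration", {
  set.seed(31)
  u <- sprintf("u%04d", 1:800)
  ids <- sprintf("T%02d", 1:40)
  sets <- lapply(1:40, function(i) sample(u, sample(5:60, 1)))
  col <- makeCollection(ids, sets)
  kept <- filterTerms(col, 15, 40, u)
  manual <- ids[vapply(sets, function(s)
    length(intersect(s, u)) >= 15 && length(intersect(s, u)) <= 40, TRUE)]
  expect_setequal(names(kept), manual)
})

test_that("hypergeometric p-values match closed forms", {
  u <- sprintf("u%02d", 1:20)
  col <- makeCollection("T1", list(u[1:5]))
  colF <- filterTerms(col, 1, 20, u)
  # full containment: P = 1 / C(20, 5)
  r <- hypergeomEnrich(u[1:5], colF)
  expect_equal(r$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$k, 5)

  # zero overlap: upper tail at zero is 1
  r0 <- hypergeomEnrich(u[6:10], colF)
  expect_equal(r0$p, 1)

  # enrichment ratio from its definition
  u2 <- sprintf("v%03d", 1:100)
  col2 <- filterTerms(makeCollection("T2", list(u2[1:8])), 1, 100, u2)
  r2 <- hypergeomEnrich(c(u2[1:4], u2[90:95]), col2)
  expect_equal(r2$k, 4)
  expect_equal(r2$ratio, (4 / 10) / (8 / 100))
})

test_that("p is non-increasing in the overlap k", {
  ps <- sapply(0:8, function(k) {
    u <- sprintf("u%03d", 1:100)
    col <- filterTerms(makeCollection("T", list(u[1:20])), 1, 100, u)
    q <- c(u[seq_len(k)], u[80:(91 - k)])  # k in-term, rest outside
    hypergeomEnrich(q, col)$p
  })
  expect_true(all(diff(ps) <= 1e-14))
})

test_that("relabeling genes consistently leaves enrichment unchanged", {
  set.seed(7)
  u <- sprintf("u%03d", 1:200)
  sets <- lapply(1:10, function(i) sample(u, 25))
  col <- filterTerms(makeCollection(sprintf("T%02d", 1:10), sets), 1, 200, u)
  q <- sample(u, 30)
  r1 <- hypergeomEnrich(q, col)
  perm <- setNames(sample(u), u)
  colP <- filterTerms(makeCollection(sprintf("T%02d", 1:10),
                                     lapply(sets, function(s)
                                       unname(perm[s]))), 1, 200,
                      unname(perm))
  r2 <- hypergeomEnrich(unname(perm[q]), colP)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$k, r2$k)
})

test_that("BH families are per query and namespace", {
  set.seed(9)
  u <- sprintf("u%03d", 1:300)
  ns <- rep(c("BP", "CC"), each = 6)
  sets <- lapply(1:12, function(i) sample(u, 20))
  col <- filterTerms(makeCollection(sprintf("T%02d", 1:12), sets, ns),
                     1, 300, u)
  r <- hypergeomEnrich(sample(u, 40), col)
  for (n in c("BP", "CC")) {
    j <- r$namespace == n
    expect_equal(r$p_adj[j], p.adjust(r$p[j], "BH"))
  }
})

test_that("out-of-universe query genes are dropped with a warning", {
  u <- sprintf("u%02d", 1:30)
  col <- filterTerms(makeCollection("T", list(u[1:10])), 1, 30, u)
  expect_warning(r <- hypergeomEnrich(c(u[1:5], "alien"), col), "dropped")
  expect_equal(r$n, 5)
  expect_error(hypergeomEnrich(character(), col), "empty query")
})

test_that("null queries keep the raw positive rate near nominal", {
  set.seed(77)
  u <- sprintf("u%04d", 1:2000)
  sets <- lapply(1:200, function(i) sample(u, sample(15:100, 1)))
  col <- filterTerms(makeCollection(sprintf("T%03d", 1:200), sets),
                     15, 400, u)
  ps <- unlist(lapply(1:50, function(i)
    hypergeomEnrich(sample(u, 60), col, queryId = paste0("q", i))$p))
  expect_equal(length(ps), 10000)
  expect_lte(mean(ps <= 0.05), 0.07)
})

test_that("planted active terms are recovered with controlled FDP", {
  recov <- fdp <- numeric(50)
  for (s in 1:50) {
    tr <- synthTruth(3000, deFraction = 0.1, seed = 500 + s)
    gs <- simulateGeneSets(tr, nTerms = 60, sizeRange = c(15, 60),
                           nActive = 10)
    universe <- names(tr@theta)
    col <- filterTerms(gs$geneSets, 15, 400, universe)
    query <- names(tr@theta)[tr@theta != 0]
    r <- hypergeomEnrich(query, col)
    hits <- r$term_id[r$significant]
    active <- intersect(gs$truth@activeTerms, r$term_id)
    recov[s] <- mean(active %in% hits)
    fdp[s] <- if (length(hits)) mean(!hits %in% active) else 0
  }
  expect_gte(mean(recov), 0.8)
  expect_lte(mean(fdp), 0.1)
})

test_that("GMT files round-trip with namespaces", {
  col <- makeCollection(c("A", "B"), list(letters[1:5], letters[3:9]),
                        ns = c("BP", "MF"))
  f <- tempfile(fileext = ".gmt")
  writeGmt(col, f)
  back <- readGmt(f)
  expect_identical(names(back), c("A", "B"))
  expect_identical(geneSets(back), geneSets(col))
  expect_identical(back@namespace, c("BP", "MF"))
})
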