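# Cross-mixture transcriptional comparison: direction concordance over the
# DEG union, through-the-origin effect-ratio regression, heatmap structure
# (k-means gene clusters, hierarchical treatment order), and treatment-level
# PCA on the DEG log2FC matrix.

#' Log2FC matrix over the union of DEGs
#'
#' One column per contrast, restricted to genes that are a DEG (at the
#' stated thresholds) in at least one contrast. Cells where a gene was
#' untestable in a contrast are NA; [heatmapStructure()] and
#' [pcaTreatments()] render those as 0 (no measured change) and record
#' which cells were imputed.
#'
#' @param contrasts named list of [ContrastResult-class] (or data.frames);
#'   names become treatment labels (defaults to contrast names).
#' @param lfcMin,padjMax DEG thresholds defining the union.
#' @return numeric matrix gene x treatment with attributes
#'   \code{lfcMin}, \code{padjMax}.
#' @export
buildLfcMatrix <- function(contrasts, lfcMin = 1, padjMax = 0.05) {
  stopifnot(length(contrasts) >= 2)
  if (is.null(names(contrasts)))
    names(contrasts) <- vapply(contrasts, function(cc)
      if (is(cc, "ContrastResult")) contrastName(cc) else "", "")
  degs <- lapply(contrasts, classifyDegs, lfcMin = lfcMin, padjMax = padjMax)
  union <- sort(unique(unlist(lapply(degs, degGenes))))
  if (!length(union)) {
    m <- matrix(numeric(0), 0, length(contrasts),
                dimnames = list(NULL, names(contrasts)))
    attr(m, "lfcMin") <- lfcMin
    attr(m, "padjMax") <- padjMax
    return(m)
  }
  m <- sapply(contrasts, function(cc) {
    df <- if (is(cc, "ContrastResult")) cc@results else cc
    df$log2FC[match(union, df$gene_id)]
  })
  m <- matrix(m, nrow = length(union),
              dimnames = list(union, names(contrasts)))
  attr(m, "lfcMin") <- lfcMin
  attr(m, "padjMax") <- padjMax
  m
}

#' Direction concordance between two contrasts over the DEG union
#'
#' A gene is discordant when its log2FC signs differ between the contrasts
#' (both nonzero); "discordant and both significant" additionally requires
#' DEG membership in both contrasts. Genes of the union missing from a
#' contrast are counted as non-discordant and reported.
#'
#' @param cA,cB two [ContrastResult-class] objects (or data.frames with
#'   gene_id, log2FC, p_adj).
#' @param lfcMin,padjMax thresholds defining the DEG union.
#' @return list: n_union, n_discordant, n_discordant_both_significant,
#'   n_missing.
#' @export
directionConcordance <- function(cA, cB, lfcMin = 1, padjMax = 0.05) {
  dfA <- if (is(cA, "ContrastResult")) cA@results else cA
  dfB <- if (is(cB, "ContrastResult")) cB@results else cB
  degA <- degGenes(classifyDegs(dfA, lfcMin, padjMax))
  degB <- degGenes(classifyDegs(dfB, lfcMin, padjMax))
  union <- sort(unique(c(degA, degB)))
  lA <- dfA$log2FC[match(union, dfA$gene_id)]
  lB <- dfB$log2FC[match(union, dfB$gene_id)]
  present <- !is.na(lA) & !is.na(lB)
  disc <- present & sign(lA) != sign(lB) & lA != 0 & lB != 0
  both <- disc & union %in% degA & union %in% degB
  list(n_union = length(union),
       n_discordant = sum(disc),
       n_discordant_both_significant = sum(both),
       n_missing = sum(!present))
}

#' Linear regression through the origin
#'
#' Fits \code{y = b x} with no intercept: \code{b = sum(xy)/sum(x^2)},
#' \code{SE = sqrt((RSS/(n-1))/sum(x^2))}, 95 percent CI
#' \code{b +/- t(0.975, n-1) * SE}, and the no-intercept coefficient of
#' determination \code{r2 = 1 - RSS/sum(y^2)}. Pairs with a missing value
#' are dropped and counted. Used to estimate the scalar ratio between two
#' mixtures' per-gene transcriptional effects.
#'
#' @param x,y paired numeric vectors (x = reference mixture's log2FCs).
#' @param level confidence level (default 0.95).
#' @return list: slope, se, ci (length 2), r2, n, n_dropped.
#' @export
originRegression <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  nDropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("x is all zero; slope undefined")
  b <- sum(x * y) / sxx
  rss <- sum((y - b * x)^2)
  se <- sqrt((rss / (n - 1)) / sxx)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  syy <- sum(y^2)
  r2 <- if (syy == 0) NA_real_ else 1 - rss / syy
  list(slope = b, se = se, ci = c(b - tq * se, b + tq * se),
       r2 = r2, n = n, n_dropped = nDropped)
}

# Random-partition k-means initialization: assign rows to k groups at
# random, start Lloyd iterations from the partition means. Returns NULL if
# the start degenerates (duplicate or empty centers).
.kmeansOneStart <- function(m, k, seed) {
  set.seed(seed)
  part <- sample(rep_len(seq_len(k), nrow(m)))
  centers <- rowsum(m, part) / as.vector(table(part))
  if (anyDuplicated(centers)) return(NULL)
  tryCatch(suppressWarnings(
    kmeans(m, centers = centers, iter.max = 100, algorithm = "Lloyd")),
    error = function(e) NULL)
}

#' Heatmap structure: k-means gene clusters + hierarchical treatment order
#'
#' Rows (genes) are clustered by k-means with \code{k} clusters, keeping
#' the best of \code{starts} random-partition Lloyd runs by total
#' within-cluster sum of squares; per-start seeds are derived from
#' \code{seed} so the result is reproducible. Treatment columns are ordered
#' by average-linkage hierarchical clustering on Euclidean distances.
#' Missing cells are imputed as 0 (gene showed no measured change in that
#' contrast) and recorded.
#'
#' @param lfc gene x treatment log2FC matrix (from [buildLfcMatrix()]).
#' @param k number of gene clusters (default 8; must be < number of genes).
#' @param starts number of random starts (default 500).
#' @param seed master seed for the per-start streams.
#' @return list: cluster (named gene -> cluster id), treatment_order,
#'   cluster_summary (data.frame cluster x treatment with mean |log2FC| and
#'   mean log2FC), tot_withinss, n_imputed.
#' @export
heatmapStructure <- function(lfc, k = 8, starts = 500, seed = 1L) {
  m <- as.matrix(lfc)
  if (k >= nrow(m)) stop("k must be smaller than the number of genes")
  nImp <- sum(is.na(m))
  m[is.na(m)] <- 0
  best <- NULL
  for (i in seq_len(starts)) {
    fit <- .kmeansOneStart(m, k, deriveSeed(seed, 100L + i))
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) stop("k-means failed in every start")
  hc <- hclust(dist(t(m)), method = "average")
  ord <- colnames(m)[hc$order]
  cl <- setNames(best$cluster, rownames(m))
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(ci) {
    sub <- m[cl == ci, , drop = FALSE]
    data.frame(cluster = ci, treatment = colnames(m),
               mean_abs_lfc = colMeans(abs(sub)),
               mean_lfc = colMeans(sub), n_genes = nrow(sub),
               row.names = NULL)
  }))
  list(cluster = cl, treatment_order = ord, cluster_summary = summ,
       tot_withinss = best$tot.withinss, n_imputed = nImp,
       treatment_hclust = hc)
}

#' PCA of treatments in DEG log2FC space
#'
#' PCA of the treatment x gene matrix (genes as features, centered, not
#' scaled). Variance fractions are eigenvalue shares and sum to 1 over the
#' returned components.
#'
#' @param lfc gene x treatment log2FC matrix; NA imputed as 0.
#' @return list: coordinates (treatment x PC), variance_fractions.
#' @export
pcaTreatments <- function(lfc) {
  m <- as.matrix(lfc)
  if (ncol(m) < 3) stop("need >= 3 treatments")
  m[is.na(m)] <- 0
  tm <- t(m)
  if (all(apply(tm, 2, var) == 0)) stop("constant matrix; PCA undefined")
  pc <- prcomp(tm, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, variance_fractions = fr)
}
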