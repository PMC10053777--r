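# Negative-binomial differential expression with a single dispersion shared
# across all treatment groups, preceded by an MDS-based sample outlier
# screen. The NB model is var = mu + alpha * mu^2 throughout.

#' Median-of-ratios size factors
#'
#' Each sample's size factor is the median ratio of its counts to the
#' per-gene geometric-mean pseudo-reference, computed over genes with all
#' counts positive. When fewer than \code{minPositive} such genes exist the
#' estimator falls back to library-size ratios (total counts scaled to
#' geometric mean 1).
#'
#' @param x a [MixtureExperiment-class] or count matrix.
#' @param minPositive minimum number of all-positive genes for the
#'   median-of-ratios route.
#' @return named numeric of per-sample size factors (geometric mean 1 in
#'   the fallback; median-of-ratios otherwise).
#' @export
estimateSizeFactors <- function(x, minPositive = 50) {
  cts <- if (is(x, "MixtureExperiment")) counts(x) else as.matrix(x)
  pos <- rowSums(cts > 0) == ncol(cts)
  if (sum(pos) >= minPositive) {
    lg <- log(cts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  } else {
    libs <- colSums(cts)
    if (any(libs == 0)) stop("sample with zero total counts")
    sf <- libs / exp(mean(log(libs)))
  }
  setNames(sf, colnames(cts))
}

#' MDS sample screen with robust outlier flagging
#'
#' Classical (metric) MDS -- the eigendecomposition of the double-centered
#' squared-distance matrix -- on Euclidean distances between samples in
#' log2(CPM + 1) space. A sample is flagged when its distance to its group
#' centroid (in the returned MDS coordinates) exceeds
#' \code{median + madMultiplier * MAD} of within-group centroid distances
#' pooled across all groups. Flagged samples are reported; removal is the
#' caller's choice.
#'
#' @param x a [MixtureExperiment-class], or count matrix with \code{group}.
#' @param group group labels when \code{x} is a matrix.
#' @param dims number of MDS dimensions (default 2).
#' @param madMultiplier robustness multiplier on the MAD (default 3).
#' @return data.frame: sample, dim1..dimK, group, dist_to_centroid,
#'   outlier_flag.
#' @export
mdsScreen <- function(x, group = NULL, dims = 2, madMultiplier = 3) {
  inp <- .asCountInput(x, group)
  cts <- inp$counts
  if (ncol(cts) < 3) stop("need at least 3 samples")
  if (ncol(cts) <= dims) stop("need more samples than MDS dimensions")
  libs <- pmax(colSums(cts), 1)
  lcpm <- log2(t(t(cts) / libs) * 1e6 + 1)
  d <- dist(t(lcpm))
  coords <- suppressWarnings(cmdscale(d, k = dims))
  if (ncol(coords) < dims)  # degenerate geometry: pad dropped axes with 0
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  grp <- inp$group
  cen <- apply(coords, 2, function(col) tapply(col, grp, mean))
  cen <- matrix(cen, nrow = length(unique(grp)),
                dimnames = list(sort(unique(grp)), NULL))
  dd <- sqrt(rowSums((coords - cen[grp, , drop = FALSE])^2))
  thr <- median(dd) + madMultiplier * mad(dd)
  out <- data.frame(sample = colnames(cts), coords, group = grp,
                    dist_to_centroid = dd, outlier_flag = dd > thr,
                    row.names = NULL)
  names(out)[2:(1 + dims)] <- paste0("dim", seq_len(dims))
  out
}

# Plug-in group means on the size-factor scale: qhat_g,group = sum(y)/sum(s),
# so mu_gj = qhat * s_j. Returns the mu matrix for genes kept (positive
# total in every group) plus the group index.
.pluginMu <- function(cts, grp, sf) {
  groups <- unique(grp)
  q <- sapply(groups, function(g) {
    j <- grp == g
    rowSums(cts[, j, drop = FALSE]) / sum(sf[j])
  })
  keep <- rowSums(q > 0) == length(groups)
  mu <- matrix(0, sum(keep), length(grp))
  for (g in groups) {
    j <- grp == g
    mu[, j] <- q[keep, g] %o% sf[j]
  }
  list(mu = mu, y = cts[keep, , drop = FALSE], grp = grp, keep = keep)
}

#' Estimate a common NB dispersion across all genes and groups
#'
#' Maximizes the Cox-Reid adjusted profile likelihood for one shared
#' dispersion alpha, with group means plugged in per gene: the NB
#' log-likelihood at \code{mu_gj = qhat_g,group * s_j} minus
#' \code{0.5 * log det(X'WX)} per gene (here, with one mean per group, half
#' the log of each group's summed working weights). The adjustment removes
#' the downward bias the estimated group means would otherwise induce at
#' small replicate numbers. Optimization is a coarse grid on log10(alpha)
#' followed by Brent refinement in the bracketing interval.
#'
#' @param x a [MixtureExperiment-class] or count matrix.
#' @param group group labels when \code{x} is a matrix.
#' @param sizeFactors optional precomputed size factors.
#' @param alphaRange search range for alpha.
#' @return the common dispersion estimate (single nonnegative number).
#' @export
estimateCommonDispersion <- function(x, group = NULL, sizeFactors = NULL,
                                     alphaRange = c(1e-4, 10)) {
  inp <- .asCountInput(x, group)
  cts <- inp$counts; grp <- inp$group
  reps <- table(grp)
  if (sum(reps >= 2) < 2)
    stop("dispersion not estimable: need >= 2 groups with >= 2 replicates")
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(cts)
  pl <- .pluginMu(cts, grp, sizeFactors)
  if (!nrow(pl$mu)) stop("no gene has positive counts in every group")
  groups <- unique(grp)
  groupCols <- lapply(groups, function(g) which(grp == g))
  apl <- function(alpha) {
    ll <- sum(dnbinom(pl$y, size = 1 / alpha, mu = pl$mu, log = TRUE))
    w <- pl$mu / (1 + alpha * pl$mu)
    cr <- 0
    for (j in groupCols)
      cr <- cr + sum(log(rowSums(w[, j, drop = FALSE])))
    ll - 0.5 * cr
  }
  lgrid <- seq(log10(alphaRange[1]), log10(alphaRange[2]), length.out = 25)
  vals <- vapply(lgrid, function(l) apl(10^l), numeric(1))
  i <- which.max(vals)
  lo <- lgrid[max(1, i - 1)]; hi <- lgrid[min(length(lgrid), i + 1)]
  opt <- optimize(function(l) apl(10^l), c(lo, hi), maximum = TRUE,
                  tol = 1e-4)
  alpha <- 10^opt$maximum
  # boundary at the low end means no detectable extra-Poisson variation
  if (i == 1 && opt$maximum <= lgrid[1] + 1e-6) alpha <- 0
  alpha
}

# One NB GLM: log link, design = intercept + treatment indicator, fixed
# dispersion, offset = log size factor. Returns coefficient, SE (expected
# information, dispersion 1), convergence flag.
.nbFitOne <- function(y, design, offset, fam) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(design, y, family = fam,
                                    offset = offset,
                                    control = list(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients))
    return(c(NA_real_, NA_real_))
  XtWX <- crossprod(design * fit$weights, design)
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(c(fit$coefficients[2], NA_real_))
  c(fit$coefficients[2], sqrt(cov[2, 2]))
}

#' Treatment-vs-control NB Wald contrast
#'
#' Per-gene NB GLM (intercept + treatment indicator, log link, offset =
#' log size factor) at a fixed common dispersion; Wald test of the
#' treatment coefficient against N(0,1); BH adjustment across all genes
#' with a non-missing p in the contrast. Genes all-zero in both groups get
#' NA throughout and do not enter the BH family. For genes all-zero in
#' exactly one group the reported log2FC uses a 0.5 pseudo-count on the
#' normalized group means (the GLM coefficient diverges); the test is still
#' the GLM Wald test.
#'
#' @param x a [MixtureExperiment-class] or count matrix.
#' @param treatment,control group labels to contrast.
#' @param alpha common NB dispersion, from [estimateCommonDispersion()].
#' @param group group labels when \code{x} is a matrix.
#' @param sizeFactors optional size factors for all samples of \code{x};
#'   computed by median-of-ratios on the two contrasted groups otherwise.
#' @return a [ContrastResult-class], rows sorted by gene id.
#' @export
nbWaldContrast <- function(x, treatment, control, alpha, group = NULL,
                           sizeFactors = NULL) {
  inp <- .asCountInput(x, group)
  stopifnot(alpha >= 0)
  sel <- inp$group %in% c(treatment, control)
  if (!any(inp$group == treatment) || !any(inp$group == control))
    stop("both contrast groups must be present")
  cts <- inp$counts[, sel, drop = FALSE]
  grp <- inp$group[sel]
  if (is.null(sizeFactors)) {
    sizeFactors <- estimateSizeFactors(cts)
  } else if (!is.null(names(sizeFactors))) {
    sizeFactors <- sizeFactors[colnames(inp$counts)][sel]
  } else {
    if (length(sizeFactors) != ncol(inp$counts))
      stop("sizeFactors must cover every sample")
    sizeFactors <- sizeFactors[sel]
  }
  if (anyNA(sizeFactors) || any(sizeFactors <= 0))
    stop("size factors must be positive and cover the contrasted samples")
  offset <- log(sizeFactors)
  design <- cbind(intercept = 1, treat = as.numeric(grp == treatment))
  fam <- if (alpha == 0) stats::poisson()
         else MASS::negative.binomial(theta = 1 / alpha)
  n <- nrow(cts)
  coef <- se <- rep(NA_real_, n)
  testable <- rowSums(cts) > 0
  for (i in which(testable)) {
    cs <- .nbFitOne(cts[i, ], design, offset, fam)
    coef[i] <- cs[1]; se[i] <- cs[2]
  }
  wald <- coef / se
  p <- 2 * pnorm(-abs(wald))
  log2fc <- coef / log(2)
  # one-group-all-zero genes: report a pseudo-counted log2FC
  normed <- t(t(cts) / sizeFactors)
  mT <- rowMeans(normed[, grp == treatment, drop = FALSE])
  mC <- rowMeans(normed[, grp == control, drop = FALSE])
  oneZero <- testable & ((mT == 0) != (mC == 0))
  log2fc[oneZero] <- log2((mT[oneZero] + 0.5) / (mC[oneZero] + 0.5))
  padj <- rep(NA_real_, n)
  ok <- !is.na(p)
  padj[ok] <- p.adjust(p[ok], method = "BH")
  res <- data.frame(gene_id = rownames(cts), log2FC = log2fc,
                    wald_stat = wald, p = p, p_adj = padj,
                    row.names = NULL)
  res <- res[order(res$gene_id), ]
  rownames(res) <- NULL
  new("ContrastResult", results = res, treatment = treatment,
      control = control, alpha = alpha,
      sizeFactors = setNames(sizeFactors, colnames(cts)))
}

#' Classify differentially expressed genes from a contrast
#'
#' Membership requires \code{|log2FC| >= lfcMin} and
#' \code{p_adj <= padjMax}. The two standard presets are
#' \code{lfcMin = 1} (heatmaps, PCA) and \code{lfcMin = 0.5} (gene-set
#' overrepresentation).
#'
#' @param contrast a [ContrastResult-class] or a data.frame with columns
#'   \code{gene_id}, \code{log2FC}, \code{p_adj}.
#' @param lfcMin absolute log2-fold-change threshold (> 0).
#' @param padjMax adjusted-p threshold (> 0).
#' @return a [DegSet-class].
#' @export
classifyDegs <- function(contrast, lfcMin = 1, padjMax = 0.05) {
  stopifnot(lfcMin >= 0, padjMax > 0)
  df <- if (is(contrast, "ContrastResult")) contrast@results else contrast
  lab <- if (is(contrast, "ContrastResult")) contrastName(contrast) else ""
  ok <- !is.na(df$log2FC) & !is.na(df$p_adj) &
    abs(df$log2FC) >= lfcMin & df$p_adj <= padjMax
  g <- df$gene_id[ok]
  new("DegSet", genes = g,
      direction = setNames(sign(df$log2FC[ok]), g),
      lfcMin = lfcMin, padjMax = padjMax, contrast = lab)
}

#' Write a contrast to TSV
#' @param contrast a [ContrastResult-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeContrastTsv <- function(contrast, path)
  .writeTsv(as.data.frame(contrast), path)

#' Read a contrast table from TSV
#' @param path a TSV with columns gene_id, log2FC, wald_stat, p, p_adj
#'   (extra columns ignored; wald_stat optional).
#' @param treatment,control labels to record on the object.
#' @return a [ContrastResult-class].
#' @export
readContrastTsv <- function(path, treatment = "treatment",
                            control = "control") {
  df <- read.delim(path)
  if (!"wald_stat" %in% names(df)) df$wald_stat <- NA_real_
  if (!"p" %in% names(df)) df$p <- NA_real_
  res <- df[, c("gene_id", "log2FC", "wald_stat", "p", "p_adj")]
  res <- res[order(res$gene_id), ]
  rownames(res) <- NULL
  new("ContrastResult", results = res, treatment = treatment,
      control = control, alpha = NA_real_, sizeFactors = numeric())
}
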