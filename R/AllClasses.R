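#' @import methods
#' @import SummarizedExperiment
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom MASS negative.binomial
#' @importFrom stats median mad dist cmdscale prcomp hclust cutree kmeans
#'   dnbinom rnbinom rpois rlnorm rnorm runif rbinom phyper pnorm qbeta qt
#'   p.adjust optimize setNames var sd fisher.test glm.fit poisson qnorm
#'   as.dist
#' @importFrom utils read.delim write.table packageVersion head combn
NULL

#' Container for a mixture-exposure count experiment
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' integer assay named \code{"counts"} (genes as rows, samples as columns)
#' and a mandatory \code{group} column in \code{colData} giving each
#' sample's treatment label. The vehicle-control group is just another
#' level of \code{group}; contrasts name it explicitly.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [MixtureExperiment()] the constructor, [sampleGroups()].
#' @export
setClass("MixtureExperiment", contains = "SummarizedExperiment")

setValidity("MixtureExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts)))
      msg <- c(msg, "counts must not contain NA")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
      if (any(cts != round(cts))) msg <- c(msg, "counts must be integral")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (any(is.na(object$group)))
    msg <- c(msg, "every sample needs a group label")
  if (length(msg)) msg else TRUE
})

#' Ground truth behind a synthetic mixture experiment
#'
#' Records every latent quantity the generators draw so that downstream
#' estimates (dispersion, per-gene effects, the cross-mixture effect
#' ratio, planted gene-set signal) can be checked against what was
#' planted. Per-gene log2 effects for the first mixture live in
#' \code{theta}; the second mixture's effects are
#' \code{beta * theta + eps} with \code{eps ~ N(0, epsSd^2)} and are
#' stored in \code{lfcB}.
#'
#' @slot theta named numeric, per-gene latent log2 effect of mixture A
#'   (0 for non-DE genes).
#' @slot lfcB named numeric, per-gene latent log2 effect of mixture B.
#' @slot beta scalar effect ratio of mixture B relative to A (unitless).
#' @slot epsSd standard deviation of the gene-level noise on B's effect.
#' @slot alpha NB dispersion, parameterized as \code{var = mu + alpha*mu^2}.
#' @slot baseMean named numeric, per-gene baseline mean at unit size factor.
#' @slot activeTerms ids of gene-set terms planted as coherently regulated.
#' @slot activeSign planted regulation sign (+1/-1) per active term.
#' @slot libSizes per-sample size factors (filled by [simulateCounts()]).
#' @slot seed master RNG seed the generator streams are derived from.
#' @export
setClass("SynthTruth", representation(
  theta = "numeric", lfcB = "numeric", beta = "numeric", epsSd = "numeric",
  alpha = "numeric", baseMean = "numeric", activeTerms = "character",
  activeSign = "numeric", libSizes = "numeric", seed = "integer"))

setValidity("SynthTruth", function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@epsSd < 0) msg <- c(msg, "epsSd must be >= 0")
  if (length(object@libSizes) && any(object@libSizes <= 0))
    msg <- c(msg, "library size factors must be positive")
  if (length(object@theta) != length(object@lfcB))
    msg <- c(msg, "theta and lfcB must have equal length")
  if (length(msg)) msg else TRUE
})

#' One treatment-vs-control differential-expression contrast
#'
#' Per-gene results of the negative-binomial Wald test: log2 fold change,
#' Wald statistic, raw and BH-adjusted p-value. Genes untestable in the
#' contrast (all-zero in both groups) carry NA and are excluded from the
#' BH family.
#'
#' @slot results data.frame with columns \code{gene_id}, \code{log2FC},
#'   \code{wald_stat}, \code{p}, \code{p_adj}, sorted by \code{gene_id}.
#' @slot treatment,control the contrasted group labels.
#' @slot alpha the common NB dispersion used in the fit.
#' @slot sizeFactors per-sample size factors used as offsets.
#' @export
setClass("ContrastResult", representation(
  results = "data.frame", treatment = "character", control = "character",
  alpha = "numeric", sizeFactors = "numeric"))

setValidity("ContrastResult", function(object) {
  msg <- character()
  need <- c("gene_id", "log2FC", "wald_stat", "p", "p_adj")
  if (!all(need %in% names(object@results)))
    return(paste("results needs columns:", paste(need, collapse = ", ")))
  p <- object@results$p; q <- object@results$p_adj
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) msg <- c(msg, "p outside [0,1]")
  if (any(q[!is.na(q)] < 0 | q[!is.na(q)] > 1)) msg <- c(msg, "p_adj outside [0,1]")
  both <- ok & !is.na(q)
  if (any(q[both] < p[both] - 1e-12)) msg <- c(msg, "p_adj must be >= p")
  if (anyDuplicated(object@results$gene_id)) msg <- c(msg, "duplicate gene ids")
  if (length(msg)) msg else TRUE
})

#' A classified set of differentially expressed genes
#'
#' Genes from one contrast passing \code{|log2FC| >= lfcMin} and
#' \code{p_adj <= padjMax}, with the regulation direction per gene.
#'
#' @slot genes member gene ids.
#' @slot direction named numeric of +1/-1 per member gene.
#' @slot lfcMin,padjMax the thresholds that defined membership.
#' @slot contrast label of the source contrast.
#' @export
setClass("DegSet", representation(
  genes = "character", direction = "numeric",
  lfcMin = "numeric", padjMax = "numeric", contrast = "character"))

setValidity("DegSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  if (length(object@direction) != length(object@genes))
    msg <- c(msg, "direction must align with genes")
  if (length(object@direction) && !all(object@direction %in% c(-1, 1)))
    msg <- c(msg, "direction must be +1/-1")
  if (length(msg)) msg else TRUE
})

#' A named collection of gene sets (GO-style terms)
#'
#' Term ids, display names, a namespace per term (BP/CC/MF), and member
#' gene ids. When built by [filterTerms()], members are restricted to the
#' declared universe and the universe is recorded.
#'
#' @slot termId unique term ids.
#' @slot termName display name per term.
#' @slot namespace one of "BP", "CC", "MF" per term.
#' @slot genes list of character vectors of member gene ids.
#' @slot universe declared gene universe (empty if unfiltered).
#' @export
setClass("GeneSetCollection", representation(
  termId = "character", termName = "character", namespace = "character",
  genes = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  n <- length(object@termId)
  if (anyDuplicated(object@termId)) msg <- c(msg, "term ids must be unique")
  if (length(object@termName) != n || length(object@namespace) != n ||
      length(object@genes) != n)
    msg <- c(msg, "slots termName/namespace/genes must align with termId")
  if (n && any(!lengths(object@genes)))
    msg <- c(msg, "member sets must be non-empty")
  if (n && !all(object@namespace %in% c("BP", "CC", "MF")))
    msg <- c(msg, "namespace must be one of BP, CC, MF")
  if (length(msg)) msg else TRUE
})

#' Enrichment-map network over significant terms
#'
#' Nodes are (term, query-set) pairs; undirected edges join term pairs
#' whose overlap coefficient on in-universe member sets meets the build
#' threshold; clusters are connected components. Components with more
#' than three terms are flagged for manual theme annotation, for which
#' free-text slots are provided.
#'
#' @slot nodes data.frame: node_id, term_id, query_id, namespace, p_adj,
#'   ratio, cluster, flagged.
#' @slot edges data.frame: source, target, coefficient.
#' @slot threshold the overlap-coefficient build threshold.
#' @slot annotations named character, free-text theme per cluster id.
#' @export
setClass("TermGraph", representation(
  nodes = "data.frame", edges = "data.frame", threshold = "numeric",
  annotations = "character"))

setValidity("TermGraph", function(object) {
  msg <- character()
  if (nrow(object@edges)) {
    if (any(object@edges$coefficient < object@threshold - 1e-12))
      msg <- c(msg, "edge below build threshold")
    if (any(object@edges$source == object@edges$target))
      msg <- c(msg, "self-loops not allowed")
  }
  if (anyDuplicated(object@nodes$node_id)) msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

#' Redundancy-reduced term-by-treatment matrix
#'
#' Result of pooling each treatment's top terms (by enrichment ratio) and
#' merging near-duplicates by complete-linkage Jaccard clustering. Each
#' original term belongs to exactly one merged term, which takes the name
#' of its smallest constituent.
#'
#' @slot summary long data.frame: merged_term, namespace, treatment,
#'   significant, best_ratio, p_adj.
#' @slot manifest data.frame mapping merged_term to its constituent term ids.
#' @slot mergeAt Jaccard-distance merge threshold.
#' @slot topN per-treatment rank cutoff used before pooling.
#' @export
setClass("ReducedTermMatrix", representation(
  summary = "data.frame", manifest = "data.frame",
  mergeAt = "numeric", topN = "numeric"))

setValidity("ReducedTermMatrix", function(object) {
  if (nrow(object@manifest) &&
      anyDuplicated(object@manifest$constituent))
    "each original term may appear in exactly one merged term" else TRUE
})
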