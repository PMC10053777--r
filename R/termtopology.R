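# Enrichment-map topology: overlap-coefficient edges between enriched
# terms, connected-component clusters, Jaccard-distance term-redundancy
# reduction, and per-cluster fold-change summaries.

#' Overlap coefficient of two gene sets
#'
#' \code{|A n B| / min(|A|, |B|)}: the enrichment-map edge weight.
#'
#' @param a,b non-empty character vectors.
#' @return value in [0, 1].
#' @export
overlapCoefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Jaccard distance of two gene sets
#'
#' \code{1 - |A n B| / |A u B|}: the metric used for term-redundancy
#' merging.
#'
#' @param a,b character vectors; their union must be non-empty.
#' @return value in [0, 1].
#' @export
jaccardDistance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (!u) stop("both sets are empty")
  1 - length(intersect(a, b)) / u
}

#' Build the enrichment-map network over significant terms
#'
#' One node per (term, query set); an undirected edge joins two nodes
#' whose terms' in-universe member sets have overlap coefficient >=
#' \code{threshold} (no self-loops between a term and itself under two
#' queries is a special case: those nodes share all genes and are joined
#' by a coefficient-1 edge). Clusters are the connected components;
#' components with more than three terms are flagged for manual theme
#' annotation.
#'
#' @param rows enrichment rows (see [hypergeomEnrich()]); only rows with
#'   \code{significant == TRUE} become nodes.
#' @param collection the [GeneSetCollection-class] the rows reference.
#' @param threshold overlap-coefficient edge threshold (default 0.4).
#' @return a [TermGraph-class].
#' @export
buildEnrichmentMap <- function(rows, collection, threshold = 0.4) {
  stopifnot(is(collection, "GeneSetCollection"))
  rows <- rows[rows$significant %in% TRUE, , drop = FALSE]
  miss <- setdiff(rows$term_id, collection@termId)
  if (length(miss)) stop("rows reference terms absent from the collection: ",
                         paste(head(miss, 5), collapse = ", "))
  nodes <- data.frame(
    node_id = paste(rows$term_id, rows$query_id, sep = "@"),
    term_id = rows$term_id, query_id = rows$query_id,
    namespace = rows$namespace, p_adj = rows$p_adj, ratio = rows$ratio,
    row.names = NULL)
  sets <- geneSets(collection)
  if (length(collection@universe))
    sets <- lapply(sets, intersect, y = collection@universe)
  edges <- data.frame(source = character(), target = character(),
                      coefficient = numeric())
  n <- nrow(nodes)
  if (n > 1) {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    coef <- vapply(seq_len(nrow(idx)), function(r) {
      i <- idx[r, 1]; j <- idx[r, 2]
      overlapCoefficient(sets[[nodes$term_id[i]]], sets[[nodes$term_id[j]]])
    }, numeric(1))
    keep <- coef >= threshold
    edges <- data.frame(source = nodes$node_id[idx[keep, 1]],
                        target = nodes$node_id[idx[keep, 2]],
                        coefficient = coef[keep], row.names = NULL)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$node_id)
  comp <- igraph::components(g)
  nodes$cluster <- as.integer(comp$membership[nodes$node_id])
  clSize <- table(nodes$cluster)
  nodes$flagged <- as.vector(clSize[as.character(nodes$cluster)]) > 3
  new("TermGraph", nodes = nodes, edges = edges, threshold = threshold,
      annotations = character())
}

#' Redundancy reduction of enriched terms by Jaccard merging
#'
#' Within each treatment (and, by default, namespace), significant terms
#' are ranked by enrichment ratio and the top \code{topN} kept. The kept
#' terms are pooled across treatments and clustered hierarchically
#' (complete linkage) on pairwise Jaccard distances of their in-universe
#' member sets; groups whose terms all sit within Jaccard distance <
#' \code{mergeAt} of each other are combined into one merged term named
#' after the smallest constituent (fewest in-universe genes; ties broken
#' lexicographically by term id). The summary reports, per treatment,
#' whether any constituent was significant, the best (max) enrichment
#' ratio, and the smallest adjusted p.
#'
#' @param rows enrichment rows pooled over treatments; \code{query_id}
#'   is the treatment label.
#' @param collection the referenced [GeneSetCollection-class].
#' @param topN per-treatment(-namespace) rank cutoff (default 60).
#' @param mergeAt Jaccard-distance merge threshold (default 0.45; strict
#'   "<").
#' @param perNamespace rank and merge within namespace (default TRUE);
#'   FALSE pools namespaces.
#' @return a [ReducedTermMatrix-class].
#' @export
reduceTerms <- function(rows, collection, topN = 60, mergeAt = 0.45,
                        perNamespace = TRUE) {
  stopifnot(is(collection, "GeneSetCollection"))
  rows <- rows[rows$significant %in% TRUE, , drop = FALSE]
  empty <- new("ReducedTermMatrix",
               summary = data.frame(merged_term = character(),
                                    namespace = character(),
                                    treatment = character(),
                                    significant = logical(),
                                    best_ratio = numeric(),
                                    p_adj = numeric()),
               manifest = data.frame(merged_term = character(),
                                     constituent = character()),
               mergeAt = mergeAt, topN = topN)
  if (!nrow(rows)) return(empty)
  sets <- geneSets(collection)
  if (length(collection@universe))
    sets <- lapply(sets, intersect, y = collection@universe)
  # deterministic top-N: ratio descending, term id as tie-break
  fam <- if (perNamespace) interaction(rows$query_id, rows$namespace,
                                       drop = TRUE)
         else factor(rows$query_id)
  kept <- do.call(rbind, lapply(split(rows, fam), function(d) {
    d <- d[order(-d$ratio, d$term_id), , drop = FALSE]
    head(d, topN)
  }))
  nsGroups <- if (perNamespace) split(kept, kept$namespace)
              else list(all = kept)
  summaries <- list(); manifests <- list()
  for (nsName in names(nsGroups)) {
    d <- nsGroups[[nsName]]
    terms <- sort(unique(d$term_id))
    if (!length(terms)) next
    groups <- if (length(terms) == 1) setNames(1L, terms) else {
      dm <- matrix(0, length(terms), length(terms),
                   dimnames = list(terms, terms))
      for (i in seq_along(terms))
        for (j in seq_len(i - 1)) {
          dm[i, j] <- dm[j, i] <-
            jaccardDistance(sets[[terms[i]]], sets[[terms[j]]])
        }
      hc <- hclust(stats::as.dist(dm), method = "complete")
      cutree(hc, h = mergeAt * (1 - 1e-9))
    }
    for (gi in unique(groups)) {
      members <- names(groups)[groups == gi]
      szs <- lengths(sets[members])
      name <- members[order(szs, members)][1]
      manifests[[length(manifests) + 1]] <-
        data.frame(merged_term = name, namespace = nsName,
                   constituent = sort(members))
      sub <- d[d$term_id %in% members, , drop = FALSE]
      per <- do.call(rbind, lapply(split(sub, sub$query_id, drop = TRUE),
                                   function(s)
        data.frame(merged_term = name, namespace = nsName,
                   treatment = s$query_id[1], significant = TRUE,
                   best_ratio = max(s$ratio), p_adj = min(s$p_adj))))
      summaries[[length(summaries) + 1]] <- per
    }
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  manifest <- do.call(rbind, manifests)
  rownames(manifest) <- NULL
  new("ReducedTermMatrix", summary = summary, manifest = manifest,
      mergeAt = mergeAt, topN = topN)
}

#' Fold-change summary of one enrichment-map cluster
#'
#' Over the union of the cluster's member terms' genes, intersected with
#' the DEGs of a contrast: mean |log2FC|, mean log2FC, gene count, and the
#' fraction down-regulated.
#'
#' @param graph a [TermGraph-class].
#' @param clusterId cluster id to summarize.
#' @param collection the referenced [GeneSetCollection-class].
#' @param contrast a [ContrastResult-class] (or data.frame with gene_id,
#'   log2FC, p_adj).
#' @param degs a [DegSet-class] for the contrast (or character vector);
#'   NULL uses all genes of the contrast with finite log2FC.
#' @return list: mean_abs_lfc, mean_lfc, n_genes, frac_down (all NA with
#'   n_genes = 0 when the gene set is empty).
#' @export
clusterMeanLfc <- function(graph, clusterId, collection, contrast,
                           degs = NULL) {
  stopifnot(is(graph, "TermGraph"))
  nd <- graph@nodes
  if (!clusterId %in% nd$cluster) stop("no such cluster: ", clusterId)
  terms <- unique(nd$term_id[nd$cluster == clusterId])
  sets <- geneSets(collection)
  if (length(collection@universe))
    sets <- lapply(sets, intersect, y = collection@universe)
  genes <- unique(unlist(sets[terms]))
  df <- if (is(contrast, "ContrastResult")) contrast@results else contrast
  if (!is.null(degs)) {
    dg <- if (is(degs, "DegSet")) degGenes(degs) else as.character(degs)
    genes <- intersect(genes, dg)
  }
  lfc <- df$log2FC[match(genes, df$gene_id)]
  lfc <- lfc[is.finite(lfc)]
  if (!length(lfc))
    return(list(mean_abs_lfc = NA_real_, mean_lfc = NA_real_,
                n_genes = 0L, frac_down = NA_real_))
  list(mean_abs_lfc = mean(abs(lfc)), mean_lfc = mean(lfc),
       n_genes = length(lfc), frac_down = mean(lfc < 0))
}

#' Write a TermGraph to GraphML and TSV
#'
#' @param graph a [TermGraph-class].
#' @param prefix output path prefix; writes \code{<prefix>.graphml},
#'   \code{<prefix>_edges.tsv}, \code{<prefix>_nodes.tsv}.
#' @return invisibly, the written paths.
#' @export
writeTermGraph <- function(graph, prefix) {
  stopifnot(is(graph, "TermGraph"))
  g <- igraph::graph_from_data_frame(graph@edges, directed = FALSE,
                                     vertices = graph@nodes$node_id)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  e <- paste0(prefix, "_edges.tsv"); n <- paste0(prefix, "_nodes.tsv")
  .writeTsv(graph@edges, e)
  .writeTsv(graph@nodes, n)
  invisible(c(gml, e, n))
}
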