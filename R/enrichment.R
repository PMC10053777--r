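# Gene-set overrepresentation: three-way DEG partition, term-size
# filtering against a declared universe, and the upper-tail hypergeometric
# test with BH control within each (query, namespace) family.

#' Partition two DEG sets into exclusive and shared groups
#'
#' @param setA,setB [DegSet-class] objects or character vectors of gene ids.
#' @return list of character vectors: \code{A_only}, \code{overlap},
#'   \code{B_only}; three disjoint sets whose union is setA U setB.
#' @export
partitionDegs <- function(setA, setB) {
  a <- if (is(setA, "DegSet")) degGenes(setA) else as.character(setA)
  b <- if (is(setB, "DegSet")) degGenes(setB) else as.character(setB)
  list(A_only = sort(setdiff(a, b)),
       overlap = sort(intersect(a, b)),
       B_only = sort(setdiff(b, a)))
}

#' Filter a gene-set collection by in-universe term size
#'
#' Members are intersected with the universe first; only terms whose
#' in-universe size is within \code{[minSize, maxSize]} (inclusive) are
#' retained, dropping overly narrow or broad terms. The returned
#' collection's member sets are the in-universe intersections and the
#' universe is recorded.
#'
#' @param collection a [GeneSetCollection-class].
#' @param minSize,maxSize inclusive size bounds (defaults 15 and 400).
#' @param universe character vector of gene ids.
#' @return a filtered [GeneSetCollection-class].
#' @export
filterTerms <- function(collection, minSize = 15, maxSize = 400, universe) {
  stopifnot(is(collection, "GeneSetCollection"), length(universe) > 0)
  if (minSize > maxSize) stop("minSize must be <= maxSize")
  inUniv <- lapply(collection@genes, intersect, y = universe)
  sz <- lengths(inUniv)
  keep <- sz >= minSize & sz <= maxSize
  new("GeneSetCollection",
      termId = collection@termId[keep],
      termName = collection@termName[keep],
      namespace = collection@namespace[keep],
      genes = inUniv[keep],
      universe = as.character(universe))
}

#' Hypergeometric overrepresentation test of a query set
#'
#' For each term, with \code{N} = universe size, \code{K} = in-universe
#' term size, \code{n} = in-universe query size and \code{k} = overlap,
#' the p-value is the upper tail \code{P(X >= k)} for
#' \code{X ~ Hypergeometric(N, K, n)}. BH adjustment is applied within
#' each (query, namespace) family. The enrichment ratio is
#' \code{(k/n) / (K/N)}, observed over expected.
#'
#' @param query character vector of gene ids (or a [DegSet-class]).
#'   Genes outside the universe are dropped with a warning.
#' @param collection a filtered [GeneSetCollection-class] (see
#'   [filterTerms()]).
#' @param universe the background gene ids; defaults to the collection's
#'   recorded universe.
#' @param queryId label recorded on every row.
#' @param padjMax significance flag threshold (default 0.05).
#' @return data.frame, one row per tested term: term_id, term_name,
#'   query_id, namespace, k, n, K, N, p, p_adj, ratio, significant.
#' @export
hypergeomEnrich <- function(query, collection,
                            universe = collection@universe,
                            queryId = "query", padjMax = 0.05) {
  stopifnot(is(collection, "GeneSetCollection"))
  q <- if (is(query, "DegSet")) degGenes(query) else as.character(query)
  if (!length(q)) stop("empty query set")
  if (!length(universe)) stop("no universe: filter the collection first ",
                              "or pass one explicitly")
  drop <- setdiff(q, universe)
  if (length(drop)) {
    warning(length(drop), " query gene(s) outside the universe dropped")
    q <- intersect(q, universe)
    if (!length(q)) stop("no query genes inside the universe")
  }
  N <- length(universe)
  n <- length(q)
  members <- lapply(collection@genes, intersect, y = universe)
  K <- lengths(members)
  k <- vapply(members, function(gs) length(intersect(gs, q)), 0L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ratio <- ifelse(K > 0, (k / n) / (K / N), NA_real_)
  out <- data.frame(term_id = collection@termId,
                    term_name = collection@termName,
                    query_id = queryId,
                    namespace = collection@namespace,
                    k = k, n = n, K = K, N = N, p = p,
                    p_adj = NA_real_, ratio = ratio, row.names = NULL)
  for (ns in unique(out$namespace)) {
    j <- out$namespace == ns
    out$p_adj[j] <- p.adjust(out$p[j], method = "BH")
  }
  out$significant <- out$p_adj <= padjMax
  out
}

#' Run the overrepresentation test for several query sets
#'
#' @param queries named list of gene-id vectors (or [DegSet-class]); names
#'   become \code{query_id} values.
#' @param collection,universe,padjMax passed to [hypergeomEnrich()].
#' @return row-bound data.frame of enrichment rows; empty (0 rows) for
#'   queries that are empty.
#' @export
enrichQueries <- function(queries, collection,
                          universe = collection@universe, padjMax = 0.05) {
  stopifnot(!is.null(names(queries)))
  rows <- lapply(names(queries), function(id) {
    q <- queries[[id]]
    qq <- if (is(q, "DegSet")) degGenes(q) else as.character(q)
    if (!length(qq) || !length(collection)) return(NULL)
    hypergeomEnrich(qq, collection, universe, queryId = id,
                    padjMax = padjMax)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      query_id = character(), namespace = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      ratio = numeric(), significant = logical()))
  do.call(rbind, rows)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated; column 1 = term id,
#' column 2 = description, columns 3+ = member gene ids. The namespace is
#' taken from the description when it is one of BP/CC/MF (optionally as a
#' "NS|name" prefix), else from \code{defaultNamespace}.
#'
#' @param path GMT file path.
#' @param defaultNamespace namespace for terms without one in the
#'   description.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path, defaultNamespace = "BP") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad),
                                                      collapse = ", "))
  ids <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  ns <- rep(defaultNamespace, length(ids))
  name <- desc
  pre <- regmatches(desc, regexec("^(BP|CC|MF)\\|(.*)$", desc))
  hit <- lengths(pre) == 3
  ns[hit] <- vapply(pre[hit], `[`, "", 2)
  name[hit] <- vapply(pre[hit], `[`, "", 3)
  ns[desc %in% c("BP", "CC", "MF")] <- desc[desc %in% c("BP", "CC", "MF")]
  genes <- lapply(parts, function(x) unique(x[-(1:2)]))
  new("GeneSetCollection", termId = ids, termName = name, namespace = ns,
      genes = genes, universe = character())
}

#' Write a gene-set collection to a GMT file
#'
#' The description column carries "namespace|term name" so [readGmt()]
#' round-trips the namespace.
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  lines <- vapply(seq_along(collection@termId), function(i) {
    paste(c(collection@termId[i],
            paste0(collection@namespace[i], "|", collection@termName[i]),
            collection@genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
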