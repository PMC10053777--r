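# Generics and small accessor/show methods for the package's S4 classes.

#' @rdname MixtureExperiment-class
#' @param object a \code{MixtureExperiment}.
#' @return \code{sampleGroups}: factor of per-sample treatment labels.
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname MixtureExperiment-class
#' @export
setMethod("sampleGroups", "MixtureExperiment", function(object)
  factor(object$group))

#' @describeIn MixtureExperiment-class the integer count assay.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "MixtureExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @rdname ContrastResult-class
#' @param x,object a \code{ContrastResult}.
#' @param ... unused.
#' @return \code{as.data.frame}: the per-gene results table.
#' @export
setMethod("as.data.frame", "ContrastResult", function(x, ...) x@results)

#' @describeIn ContrastResult-class contrast label, "treatment_vs_control".
#' @export
setGeneric("contrastName", function(object) standardGeneric("contrastName"))

#' @rdname ContrastResult-class
#' @export
setMethod("contrastName", "ContrastResult", function(object)
  paste0(object@treatment, "_vs_", object@control))

#' @rdname ContrastResult-class
#' @export
setMethod("show", "ContrastResult", function(object) {
  r <- object@results
  cat("ContrastResult:", contrastName(object), "\n")
  cat(" ", nrow(r), "genes,", sum(!is.na(r$p)), "tested, dispersion alpha =",
      signif(object@alpha, 4), "\n")
})

#' @rdname DegSet-class
#' @param object a \code{DegSet}.
#' @return \code{degGenes}: character vector of member gene ids.
#' @export
setGeneric("degGenes", function(object) standardGeneric("degGenes"))

#' @rdname DegSet-class
#' @export
setMethod("degGenes", "DegSet", function(object) object@genes)

#' @rdname DegSet-class
#' @param x a \code{DegSet}.
#' @export
setMethod("length", "DegSet", function(x) length(x@genes))

#' @rdname DegSet-class
#' @export
setMethod("show", "DegSet", function(object) {
  cat("DegSet (", object@contrast, "): ", length(object@genes),
      " genes at |log2FC| >= ", object@lfcMin, ", p_adj <= ",
      object@padjMax, " (", sum(object@direction > 0), " up, ",
      sum(object@direction < 0), " down)\n", sep = "")
})

#' @rdname GeneSetCollection-class
#' @param object,x a \code{GeneSetCollection}.
#' @return \code{geneSets}: named list of member-gene character vectors.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(object)
  setNames(object@genes, object@termId))

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@termId))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) x@termId)

#' @rdname GeneSetCollection-class
#' @param i term ids or indices.
#' @param j,drop unused.
#' @param ... unused.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@termId)
  new("GeneSetCollection", termId = x@termId[i], termName = x@termName[i],
      namespace = x@namespace[i], genes = x@genes[i], universe = x@universe)
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@termId), "terms")
  if (length(object@termId)) {
    sz <- lengths(object@genes)
    cat(" (sizes ", min(sz), "-", max(sz), ")", sep = "")
    cat("; namespaces:",
        paste(names(table(object@namespace)), table(object@namespace),
              sep = ":", collapse = " "))
  }
  if (length(object@universe))
    cat("; universe of", length(object@universe), "genes")
  cat("\n")
})

#' @rdname TermGraph-class
#' @param object a \code{TermGraph}.
#' @return \code{termClusters}: named integer of cluster id per node.
#' @export
setGeneric("termClusters", function(object) standardGeneric("termClusters"))

#' @rdname TermGraph-class
#' @export
setMethod("termClusters", "TermGraph", function(object)
  setNames(object@nodes$cluster, object@nodes$node_id))

#' @describeIn TermGraph-class attach a free-text theme to a cluster id.
#' @param value named character: cluster id -> theme text.
#' @export
setGeneric("annotateCluster<-", function(object, value)
  standardGeneric("annotateCluster<-"))

#' @rdname TermGraph-class
#' @export
setMethod("annotateCluster<-", "TermGraph", function(object, value) {
  stopifnot(!is.null(names(value)))
  object@annotations[names(value)] <- value
  object
})

#' @rdname TermGraph-class
#' @export
setMethod("show", "TermGraph", function(object) {
  cat("TermGraph:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges (overlap coefficient >=", object@threshold, ")\n")
  if (nrow(object@nodes)) {
    ncl <- length(unique(object@nodes$cluster))
    cat(" ", ncl, "clusters;", sum(tapply(object@nodes$flagged,
        object@nodes$cluster, any)), "flagged for annotation (>3 terms)\n")
  }
})

#' @rdname ReducedTermMatrix-class
#' @export
setMethod("show", "ReducedTermMatrix", function(object) {
  cat("ReducedTermMatrix:", length(unique(object@summary$merged_term)),
      "merged terms x", length(unique(object@summary$treatment)),
      "treatments (top", object@topN, "per treatment, merged at Jaccard <",
      object@mergeAt, ")\n")
})

#' @rdname SynthTruth-class
#' @export
setMethod("show", "SynthTruth", function(object) {
  cat("SynthTruth:", length(object@theta), "genes,",
      sum(object@theta != 0), "DE; beta =", object@beta,
      "; alpha =", object@alpha, "; seed =", object@seed, "\n")
})
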