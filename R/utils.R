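#' Derive an independent child seed from a master seed
#'
#' One master seed fans out to per-generator streams so each module can be
#' simulated and tested independently while a single integer still pins the
#' whole pipeline. The map is a fixed affine hash kept below 2^31 - 1.
#'
#' @param seed master seed (integer-like).
#' @param stream small nonnegative integer identifying the consumer.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stream = 0L) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(stream) * 7919 + 12345) %% 2147483647)
}

#' Construct a MixtureExperiment from a count matrix and group labels
#'
#' @param counts integer matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param group character/factor of treatment labels, one per sample, or a
#'   data.frame with columns \code{sample} and \code{group}.
#' @return a [MixtureExperiment-class].
#' @examples
#' m <- matrix(rpois(40, 10), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' MixtureExperiment(m, rep(c("control", "treated"), each = 2))
#' @export
MixtureExperiment <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.data.frame(group)) {
    stopifnot(all(c("sample", "group") %in% names(group)))
    idx <- match(colnames(counts), group$sample)
    if (anyNA(idx)) stop("metadata is missing samples: ",
                         paste(colnames(counts)[is.na(idx)], collapse = ", "))
    group <- group$group[idx]
  }
  if (length(group) != ncol(counts))
    stop("need one group label per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(counts)))
  new("MixtureExperiment", se)
}

#' Read a count matrix and sample metadata from TSV
#'
#' Counts TSV: genes as rows, first column gene ids, header = sample ids.
#' Metadata TSV: columns \code{sample}, \code{group}.
#'
#' @param countsFile,metaFile paths to the two TSVs.
#' @return a [MixtureExperiment-class].
#' @export
readCountsTsv <- function(countsFile, metaFile) {
  cts <- read.delim(countsFile, row.names = 1, check.names = FALSE)
  meta <- read.delim(metaFile, check.names = FALSE)
  MixtureExperiment(as.matrix(cts), meta)
}

#' Write a MixtureExperiment to counts + metadata TSVs
#'
#' @param x a [MixtureExperiment-class].
#' @param countsFile,metaFile output paths.
#' @return invisibly, the two paths.
#' @export
writeCountsTsv <- function(x, countsFile, metaFile) {
  df <- data.frame(gene_id = rownames(x), counts(x), check.names = FALSE)
  write.table(df, countsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(x),
                     group = as.character(sampleGroups(x)))
  write.table(meta, metaFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(countsFile, metaFile))
}

# Coerce user input (MixtureExperiment | matrix + group) to a standard list.
.asCountInput <- function(x, group = NULL) {
  if (is(x, "MixtureExperiment"))
    return(list(counts = counts(x), group = as.character(sampleGroups(x))))
  x <- as.matrix(x)
  if (is.null(group)) stop("supply group labels with a raw matrix")
  list(counts = x, group = as.character(group))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
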