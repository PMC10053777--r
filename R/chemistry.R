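# PAH chemistry summaries for passive-sampler extracts: totals with
# propagated t-intervals, source-diagnostic ratios, and composition
# profiles. Input is a long table of final concentrations (analyte,
# sample, concentration, optional replicate).

# per-analyte replicate means and variances for one sample
.analyteStats <- function(records, sample) {
  d <- records[records$sample == sample, , drop = FALSE]
  if (!nrow(d)) stop("no records for sample ", sample)
  if (any(d$concentration < 0)) stop("concentrations must be >= 0")
  sp <- split(d$concentration, d$analyte)
  data.frame(analyte = names(sp),
             mean = vapply(sp, mean, 0),
             var = vapply(sp, function(v)
               if (length(v) > 1) var(v) else NA_real_, 0),
             n = lengths(sp), row.names = NULL)
}

#' Total PAH concentration with a propagated confidence interval
#'
#' The total is the sum of per-analyte replicate means. Its variance is
#' the sum of per-analyte variances of the mean (independent analyte
#' errors assumed), taken from this sample's replicates or, when it has
#' none, from a designated reference sample's (the common design where one
#' site's triplicates supply the variance for both reported samples). The
#' interval is \code{total +/- t(df) * SE} with \code{df = replicates - 1}.
#' Values below \code{loq} enter the total as 0 and are flagged.
#'
#' @param records chemistry table: analyte, sample, concentration,
#'   optional replicate.
#' @param sample sample id to total.
#' @param referenceSample optional sample id supplying replicate variance
#'   when \code{sample} is unreplicated.
#' @param level confidence level (default 0.95).
#' @param loq limit of quantification; analyte means below it count 0.
#' @return list: total, se, ci (length 2 or NA), df, n_below_loq,
#'   ci_available.
#' @export
sumPah <- function(records, sample, referenceSample = NULL, level = 0.95,
                   loq = 0) {
  st <- .analyteStats(records, sample)
  below <- st$mean < loq
  st$mean[below] <- 0
  total <- sum(st$mean)
  vsrc <- st
  if (all(is.na(st$var)) && !is.null(referenceSample))
    vsrc <- .analyteStats(records, referenceSample)
  if (all(is.na(vsrc$var)))
    return(list(total = total, se = NA_real_, ci = c(NA_real_, NA_real_),
                df = NA_integer_, n_below_loq = sum(below),
                ci_available = FALSE))
  v <- vsrc$var[!is.na(vsrc$var)]
  n <- vsrc$n[!is.na(vsrc$var)]
  se <- sqrt(sum(v / n))
  df <- min(n) - 1
  tq <- qt(1 - (1 - level) / 2, df)
  list(total = total, se = se, ci = c(total - tq * se, total + tq * se),
       df = df, n_below_loq = sum(below), ci_available = TRUE)
}

#' Source-diagnostic PAH ratios
#'
#' The fluoranthene/pyrene, retene/chrysene and phenanthrene/anthracene
#' ratios per sample, plus -- when two samples are given -- the
#' between-sample relative difference \code{|rA - rB| / mean(r)} per
#' ratio. Near-equal ratios across samples indicate a shared contamination
#' source regardless of overall concentration.
#'
#' @param records chemistry table (see [sumPah()]).
#' @param samples one or two sample ids.
#' @param pairs named list of analyte pairs; default FLA/PYR, RET/CHR,
#'   PHE/ANT.
#' @param loq analyte means below this are excluded from ratios (ratio
#'   flagged missing).
#' @return data.frame: ratio, one column per sample, and
#'   \code{relative_difference} when two samples are given.
#' @export
diagnosticRatios <- function(records, samples,
                             pairs = list(`FLA/PYR` = c("FLA", "PYR"),
                                          `RET/CHR` = c("RET", "CHR"),
                                          `PHE/ANT` = c("PHE", "ANT")),
                             loq = 0) {
  stopifnot(length(samples) %in% 1:2)
  one <- function(smp) {
    st <- .analyteStats(records, smp)
    means <- setNames(st$mean, st$analyte)
    means[means < loq] <- NA
    vapply(pairs, function(pr) {
      num <- means[pr[1]]; den <- means[pr[2]]
      if (is.na(num) || is.na(den) || !length(num) || !length(den) ||
          den <= 0) NA_real_ else unname(num / den)
    }, numeric(1))
  }
  out <- data.frame(ratio = names(pairs))
  for (smp in samples) out[[smp]] <- one(smp)
  if (length(samples) == 2) {
    rA <- out[[samples[1]]]; rB <- out[[samples[2]]]
    out$relative_difference <- abs(rA - rB) / ((rA + rB) / 2)
  }
  out
}

#' Composition profile of a sample
#'
#' Per-analyte proportion of the total concentration; proportions sum
#' to 1 and are invariant to uniform scaling of the sample.
#'
#' @param records chemistry table (see [sumPah()]).
#' @param sample sample id.
#' @return data.frame: analyte, proportion.
#' @export
compositionProfile <- function(records, sample) {
  st <- .analyteStats(records, sample)
  total <- sum(st$mean)
  if (total <= 0) stop("sample total is zero; profile undefined")
  data.frame(analyte = st$analyte, proportion = st$mean / total)
}
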