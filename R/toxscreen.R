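# Developmental-screen statistics: plate quality control, exact binomial
# incidence intervals, Fisher's exact between-arm comparisons, and the
# per-endpoint incidence profile at a chosen dilution.

#' Plate quality control on control mortality
#'
#' A plate fails when mortality exceeds two fish in either the negative
#' (vehicle) or positive control arm; exactly two is still a pass. Failed
#' plates are flagged for retest.
#'
#' @param plates data.frame with columns \code{plate},
#'   \code{neg_mortality}, \code{pos_mortality} (counts out of the 8
#'   control wells per arm).
#' @param maxMortality largest passing control mortality (default 2).
#' @return the input with logical columns \code{pass} and \code{retest}.
#' @export
plateQc <- function(plates, maxMortality = 2) {
  need <- c("neg_mortality", "pos_mortality")
  if (!all(need %in% names(plates)))
    stop("both control arms are required (columns ",
         paste(need, collapse = ", "), ")")
  if (any(is.na(plates[need]))) stop("control counts must not be NA")
  plates$pass <- plates$neg_mortality <= maxMortality &
    plates$pos_mortality <= maxMortality
  plates$retest <- !plates$pass
  plates
}

#' Exact (Clopper-Pearson) binomial confidence interval for an incidence
#'
#' The default is the exact interval from beta quantiles; \code{method =
#' "wilson"} gives the Wilson score interval instead.
#'
#' @param nAffected,nExposed counts (vectors recycle).
#' @param level confidence level (default 0.95).
#' @param method "clopper-pearson" (default) or "wilson".
#' @return data.frame: proportion, lo, hi.
#' @export
incidenceCi <- function(nAffected, nExposed, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (any(nExposed == 0)) stop("n_exposed must be positive")
  if (any(nAffected < 0 | nAffected > nExposed))
    stop("need 0 <= n_affected <= n_exposed")
  x <- nAffected; n <- nExposed
  p <- x / n
  a <- (1 - level) / 2
  if (method == "clopper-pearson") {
    lo <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
    hi <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  } else {
    z <- stats::qnorm(1 - a)
    den <- 1 + z^2 / n
    cen <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- pmax(0, cen - half); hi <- pmin(1, cen + half)
  }
  data.frame(proportion = p, lo = lo, hi = hi)
}

#' Two-sided Fisher's exact test on a 2x2 incidence table
#'
#' The two-sided p-value follows the probability-mass convention: the sum
#' of probabilities of all tables (at fixed margins) no more probable than
#' the observed one.
#'
#' @param aAffected,aN,bAffected,bN affected counts and totals of the two
#'   arms.
#' @return the two-sided p-value.
#' @export
fisherCompare <- function(aAffected, aN, bAffected, bN) {
  stopifnot(aAffected >= 0, aAffected <= aN, bAffected >= 0, bAffected <= bN)
  tab <- matrix(c(aAffected, aN - aAffected, bAffected, bN - bAffected),
                2, 2)
  fisher.test(tab)$p.value
}

#' Per-endpoint incidence profile at one dilution
#'
#' For every endpoint observed at the requested dilution: incidence with
#' exact CIs per treatment, Fisher's exact p against the control arm, and
#' pairwise Fisher p between treatments. Rows are sorted by the largest
#' incidence difference versus control. BH adjustment across endpoints
#' (within each comparison family) is available but off by default, since
#' single unadjusted comparisons are the screening convention.
#'
#' @param records screen table: treatment, dilution, endpoint, n_exposed,
#'   n_affected. Controls are the rows with \code{treatment == control}.
#' @param dilution the dilution (extract percent) to profile.
#' @param control control treatment label (default "control").
#' @param adjust apply BH across endpoints within each comparison family.
#' @return list: \code{profile} (endpoint x treatment incidence table with
#'   CIs and p vs control) and \code{between} (pairwise treatment
#'   comparisons per endpoint).
#' @export
endpointProfile <- function(records, dilution, control = "control",
                            adjust = FALSE) {
  ctl <- records[records$treatment == control, , drop = FALSE]
  if (!nrow(ctl)) stop("control records are required")
  sub <- records[records$treatment != control &
                   records$dilution == dilution, , drop = FALSE]
  if (!nrow(sub)) stop("no records at dilution ", dilution)
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    r <- sub[i, ]
    c0 <- ctl[ctl$endpoint == r$endpoint, , drop = FALSE]
    ci <- incidenceCi(r$n_affected, r$n_exposed)
    if (nrow(c0)) {
      c0 <- c0[1, ]
      pC <- fisherCompare(r$n_affected, r$n_exposed,
                          c0$n_affected, c0$n_exposed)
      dInc <- ci$proportion - c0$n_affected / c0$n_exposed
    } else {
      pC <- NA_real_; dInc <- NA_real_
    }
    data.frame(treatment = r$treatment, endpoint = r$endpoint,
               n_exposed = r$n_exposed, n_affected = r$n_affected,
               incidence = ci$proportion, lo = ci$lo, hi = ci$hi,
               diff_vs_control = dInc, p_vs_control = pC)
  })
  prof <- do.call(rbind, rows)
  if (adjust) {
    for (tr in unique(prof$treatment)) {
      j <- prof$treatment == tr
      prof$p_vs_control[j] <- p.adjust(prof$p_vs_control[j], "BH")
    }
  }
  prof <- prof[order(-abs(prof$diff_vs_control)), ]
  rownames(prof) <- NULL
  trts <- unique(sub$treatment)
  between <- NULL
  if (length(trts) >= 2) {
    pairs <- utils::combn(trts, 2)
    between <- do.call(rbind, lapply(unique(sub$endpoint), function(ep) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
        ra <- sub[sub$treatment == pairs[1, pi] & sub$endpoint == ep, ]
        rb <- sub[sub$treatment == pairs[2, pi] & sub$endpoint == ep, ]
        if (!nrow(ra) || !nrow(rb)) return(NULL)
        data.frame(endpoint = ep, treatment_a = pairs[1, pi],
                   treatment_b = pairs[2, pi],
                   p = fisherCompare(ra$n_affected[1], ra$n_exposed[1],
                                     rb$n_affected[1], rb$n_exposed[1]))
      }))
    }))
    if (adjust && !is.null(between)) between$p <- p.adjust(between$p, "BH")
    rownames(between) <- NULL
  }
  list(profile = prof, between = between)
}
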