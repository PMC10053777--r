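# Synthetic-data generators. These emulate the statistical structure the
# downstream analysis assumes -- NB counts for a shared vehicle control plus
# treatment groups where one mixture's per-gene log2 effects are a scalar
# multiple of the other's plus gene-level noise, gene-set collections with
# planted coherent regulation, binomial dose-response screens, and paired
# chemistry profiles differing by a scale factor -- and carry their ground
# truth for parameter-recovery tests.

#' Create the latent ground truth for a synthetic mixture experiment
#'
#' Draws per-gene baseline means and latent log2 effects. A fraction
#' \code{deFraction} of genes is differentially expressed in mixture A with
#' effects \code{theta ~ +/- Uniform(thetaRange)}; mixture B's latent effect
#' per gene is \code{beta * theta + eps}, \code{eps ~ N(0, epsSd^2)},
#' mirroring two extracts from a shared contamination source where one is a
#' scaled-down version of the other.
#'
#' @param nGenes number of genes.
#' @param deFraction fraction of genes differentially expressed in mixture A.
#' @param thetaRange range of |theta| for DE genes (log2 units).
#' @param beta scalar effect ratio of mixture B relative to mixture A.
#' @param epsSd sd of the gene-level noise on B's latent effect (log2 units).
#' @param alpha NB dispersion (\code{var = mu + alpha * mu^2}); 0 = Poisson.
#' @param baseMean per-gene baseline mean; a scalar/vector to fix it, or
#'   NULL to draw log-normal(log 100, sdlog 1).
#' @param seed master seed; generator streams are derived from it.
#' @return a [SynthTruth-class].
#' @examples
#' synthTruth(1000, seed = 7)
#' @export
synthTruth <- function(nGenes, deFraction = 0.1, thetaRange = c(0.5, 3),
                       beta = 0.59, epsSd = 0.3, alpha = 0.05,
                       baseMean = NULL, seed = 1L) {
  stopifnot(nGenes >= 1, deFraction >= 0, deFraction <= 1,
            thetaRange[1] <= thetaRange[2])
  if (alpha < 0) stop("alpha must be >= 0 (var = mu + alpha*mu^2)")
  set.seed(deriveSeed(seed, 1L))
  ids <- sprintf("g%05d", seq_len(nGenes))
  theta <- numeric(nGenes)
  nDe <- round(deFraction * nGenes)
  if (nDe > 0) {
    de <- sample.int(nGenes, nDe)
    theta[de] <- sample(c(-1, 1), nDe, replace = TRUE) *
      runif(nDe, thetaRange[1], thetaRange[2])
  }
  lfcB <- beta * theta + rnorm(nGenes, 0, epsSd)
  bm <- if (is.null(baseMean)) rlnorm(nGenes, log(100), 1)
        else rep_len(as.numeric(baseMean), nGenes)
  new("SynthTruth",
      theta = setNames(theta, ids), lfcB = setNames(lfcB, ids),
      beta = beta, epsSd = epsSd, alpha = alpha,
      baseMean = setNames(bm, ids),
      activeTerms = character(), activeSign = numeric(),
      libSizes = numeric(), seed = as.integer(seed))
}

#' Simulate an NB count matrix for control + mixture groups
#'
#' Counts are drawn \code{NB(mean = baseMean_g * s_j * 2^L_gt, dispersion
#' alpha)} where the latent log2 effect \code{L} is 0 for the control,
#' \code{theta_g} for mixture A and \code{beta*theta_g + eps_g} for mixture
#' B. Size factors \code{s_j} are drawn log-normal(0, libSdLog). Extra
#' single-chemical groups can be added through \code{extraLfc}.
#'
#' @param truth a [SynthTruth-class].
#' @param samplesPerGroup replicates per group (>= 2).
#' @param groups group labels; the first is the control (latent effect 0),
#'   the second/third get theta and beta*theta + eps respectively.
#' @param extraLfc named list of per-gene log2-effect vectors for additional
#'   treatment groups.
#' @param libSdLog sdlog of the log-normal size-factor draw.
#' @return list with \code{counts} (a [MixtureExperiment-class]) and
#'   \code{truth} (input truth with \code{libSizes} filled in).
#' @examples
#' sim <- simulateCounts(synthTruth(200, seed = 1), samplesPerGroup = 3)
#' sim$counts
#' @export
simulateCounts <- function(truth, samplesPerGroup = 3,
                           groups = c("control", "mixtureA", "mixtureB"),
                           extraLfc = NULL, libSdLog = 0.1) {
  stopifnot(is(truth, "SynthTruth"), samplesPerGroup >= 2,
            length(groups) >= 2)
  if (truth@alpha < 0) stop("negative dispersion alpha is not allowed")
  nGenes <- length(truth@theta)
  ids <- names(truth@theta)
  L <- matrix(0, nGenes, length(groups), dimnames = list(ids, groups))
  if (length(groups) >= 2) L[, 2] <- truth@theta
  if (length(groups) >= 3) L[, 3] <- truth@lfcB
  if (length(groups) > 3) {
    for (g in groups[-(1:3)]) {
      if (is.null(extraLfc[[g]]))
        stop("extraLfc must provide a log2-effect vector for group '", g, "'")
      L[, g] <- rep_len(extraLfc[[g]], nGenes)
    }
  }
  set.seed(deriveSeed(truth@seed, 2L))
  nSamp <- samplesPerGroup * length(groups)
  s <- rlnorm(nSamp, 0, libSdLog)
  if (any(s <= 0)) stop("library size factors must be positive")
  groupOf <- rep(groups, each = samplesPerGroup)
  sampleIds <- paste0(groupOf, "_", rep(seq_len(samplesPerGroup),
                                        length(groups)))
  mu <- truth@baseMean * outer(rep(1, nGenes), s) *
    2^L[, groupOf, drop = FALSE]
  cts <- if (truth@alpha == 0) {
    matrix(rpois(length(mu), lambda = mu), nGenes, nSamp)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / truth@alpha),
           nGenes, nSamp)
  }
  dimnames(cts) <- list(ids, sampleIds)
  storage.mode(cts) <- "integer"
  truth@libSizes <- setNames(s, sampleIds)
  list(counts = MixtureExperiment(cts, groupOf), truth = truth)
}

#' Simulate a gene-set collection with planted coherent regulation
#'
#' Term sizes are uniform on \code{sizeRange}. The first \code{nActive}
#' terms are "active": a fraction \code{activeCoherence} of their members is
#' drawn from DE genes sharing one regulation sign, emulating gene sets that
#' respond coherently to exposure; remaining members (and all members of
#' inactive terms) are drawn uniformly from the universe.
#'
#' @param truth a [SynthTruth-class]; planted term ids are recorded in it.
#' @param nTerms number of terms.
#' @param sizeRange inclusive term-size range (defaults 15--400, the usual
#'   window that drops overly narrow or broad terms).
#' @param universe gene ids to sample from (default: the truth's genes).
#' @param nActive number of planted coherently-regulated terms.
#' @param activeCoherence fraction of an active term drawn from same-sign
#'   DE genes (>= 0.8 keeps the planted-coherence invariant).
#' @param namespaces namespaces to assign terms to, cyclically.
#' @return list with \code{geneSets} (a [GeneSetCollection-class]) and
#'   \code{truth} (with \code{activeTerms}/\code{activeSign} filled).
#' @export
simulateGeneSets <- function(truth, nTerms = 50, sizeRange = c(15, 400),
                             universe = names(truth@theta), nActive = 10,
                             activeCoherence = 0.9,
                             namespaces = c("BP", "CC", "MF")) {
  stopifnot(is(truth, "SynthTruth"), nTerms >= 1, nActive <= nTerms,
            activeCoherence >= 0, activeCoherence <= 1)
  if (sizeRange[1] > sizeRange[2] || sizeRange[2] > length(universe))
    stop("sizeRange must fit inside the universe")
  set.seed(deriveSeed(truth@seed, 3L))
  sizes <- sizeRange[1] +
    sample.int(sizeRange[2] - sizeRange[1] + 1, nTerms, replace = TRUE) - 1L
  theta <- truth@theta[intersect(names(truth@theta), universe)]
  up <- names(theta)[theta > 0]
  down <- names(theta)[theta < 0]
  ids <- sprintf("T%04d", seq_len(nTerms))
  sign <- numeric(0)
  members <- vector("list", nTerms)
  for (i in seq_len(nTerms)) {
    if (i <= nActive) {
      s <- sample(c(-1, 1), 1)
      pool <- if (s > 0) up else down
      nCoh <- ceiling(activeCoherence * sizes[i])
      if (nCoh > length(pool)) {
        # keep the planted coherence feasible for this universe
        sizes[i] <- max(sizeRange[1], floor(length(pool) / activeCoherence))
        nCoh <- ceiling(activeCoherence * sizes[i])
        if (nCoh > length(pool))
          stop("not enough same-sign DE genes to plant an active term")
      }
      core <- sample(pool, nCoh)
      rest <- sample(setdiff(universe, core), sizes[i] - nCoh)
      members[[i]] <- c(core, rest)
      sign <- c(sign, setNames(s, ids[i]))
    } else {
      members[[i]] <- sample(universe, sizes[i])
    }
  }
  gs <- new("GeneSetCollection",
            termId = ids,
            termName = sprintf("synthetic process %d", seq_len(nTerms)),
            namespace = rep_len(namespaces, nTerms),
            genes = members, universe = character())
  truth@activeTerms <- ids[seq_len(nActive)]
  truth@activeSign <- sign
  list(geneSets = gs, truth = truth)
}

#' Default planted incidence curves for the developmental screen
#'
#' Two extracts at the standard dilution series (1, 0.2, 0.04, 0.008 percent
#' extract) with endpoints mortality, any-effect-except-mortality, and wavy
#' notochord; mixture A is the more toxic (labels match the count
#' generator, where mixture A also drives the stronger transcriptional
#' response). Planted probabilities follow the
#' characteristic pattern of a steep dose response: complete effect at the
#' 1 percent exposure, a discriminating mid dose (0.675 vs 0.265 any-effect
#' at 0.2 percent, with the wavy notochord driving mixture A's excess), and
#' background-level response at the two lowest doses.
#'
#' @return data.frame: treatment, dilution, endpoint, p.
#' @export
defaultIncidenceCurves <- function() {
  dil <- c(1, 0.2, 0.04, 0.008)
  rbind(
    data.frame(treatment = "mixtureA", dilution = dil,
               endpoint = "mortality", p = c(0.50, 0.075, 0.025, 0.025)),
    data.frame(treatment = "mixtureA", dilution = dil,
               endpoint = "any_effect", p = c(1.00, 0.675, 0.05, 0.025)),
    data.frame(treatment = "mixtureA", dilution = dil,
               endpoint = "wavy_notochord", p = c(0.60, 0.50, 0.01, 0.005)),
    data.frame(treatment = "mixtureB", dilution = dil,
               endpoint = "mortality", p = c(0.40, 0.05, 0.025, 0.025)),
    data.frame(treatment = "mixtureB", dilution = dil,
               endpoint = "any_effect", p = c(1.00, 0.265, 0.03, 0.02)),
    data.frame(treatment = "mixtureB", dilution = dil,
               endpoint = "wavy_notochord", p = c(0.10, 0.02, 0.005, 0.005)),
    data.frame(treatment = "control", dilution = 0,
               endpoint = c("mortality", "any_effect", "wavy_notochord"),
               p = c(0.0125, 0.02, 0.0025)))
}

#' Simulate a developmental-screen dose-response table
#'
#' Affected counts are Binomial(n, p) per (treatment, dilution, endpoint)
#' row of \code{curves}. A per-plate control table is generated alongside
#' for plate QC: each exposure plate carries 8 vehicle-control and 8
#' positive-control wells, with mortality drawn at realistic background
#' rates (positive-control mortality kept below the malformation-complete,
#' low-mortality regime of the reference toxicant).
#'
#' @param curves data.frame of planted probabilities (treatment, dilution,
#'   endpoint, p); default [defaultIncidenceCurves()].
#' @param nPerDose embryos per (treatment, dilution) combination
#'   (default 40, i.e. 20 per plate across two plates).
#' @param seed RNG seed.
#' @param negControlP,posControlP per-well mortality probabilities for the
#'   negative and positive control wells.
#' @return list with \code{screen} (treatment, dilution, endpoint,
#'   n_exposed, n_affected) and \code{plates} (plate, treatment, dilution,
#'   neg_mortality, pos_mortality out of 8 wells each).
#' @export
simulateToxScreen <- function(curves = defaultIncidenceCurves(),
                              nPerDose = 40, seed = 1L,
                              negControlP = 0.0125, posControlP = 0.1) {
  stopifnot(nPerDose >= 1, all(curves$p >= 0), all(curves$p <= 1))
  set.seed(deriveSeed(seed, 4L))
  screen <- data.frame(
    treatment = curves$treatment, dilution = curves$dilution,
    endpoint = curves$endpoint, n_exposed = nPerDose,
    n_affected = rbinom(nrow(curves), nPerDose, curves$p))
  combos <- unique(curves[curves$dilution > 0, c("treatment", "dilution")])
  plates <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    data.frame(plate = paste0(combos$treatment[i], "_",
                              combos$dilution[i], "_p", 1:2),
               treatment = combos$treatment[i], dilution = combos$dilution[i],
               neg_mortality = rbinom(2, 8, negControlP),
               pos_mortality = rbinom(2, 8, posControlP))
  }))
  list(screen = screen, plates = plates)
}

#' Simulate paired PAH concentration tables with a shared source profile
#'
#' Sample B's expected concentration is \code{scale} times sample A's for
#' every analyte, so source-diagnostic ratios are equal between samples in
#' expectation -- two sites contaminated from the same source at different
#' intensities. Replicate noise is log-normal with the requested
#' coefficient of variation (exact mean and CV).
#'
#' @param baseProfile named numeric, expected concentration (uM at the 1
#'   percent exposure scale) per analyte for sample A; default
#'   [defaultPahProfile()].
#' @param scale multiplicative factor for sample B (default 310/190, the
#'   total-concentration ratio the defaults are built around).
#' @param cv replicate coefficient of variation (0 = noiseless).
#' @param nReps replicates per sample.
#' @param samples the two sample ids; the first receives the base
#'   profile, the second the scaled one (defaults name the scaled, more
#'   contaminated extract "mixtureA" to match the other generators).
#' @param seed RNG seed.
#' @return data.frame: analyte, sample, replicate, concentration.
#' @export
simulateChemTable <- function(baseProfile = defaultPahProfile(),
                              scale = 310 / 190, cv = 0.05, nReps = 3,
                              samples = c("mixtureB", "mixtureA"),
                              seed = 1L) {
  if (!length(baseProfile)) stop("baseProfile must contain >= 1 analyte")
  stopifnot(scale > 0, cv >= 0, nReps >= 1, length(samples) == 2)
  set.seed(deriveSeed(seed, 5L))
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mean) {
    if (cv == 0) rep(mean, nReps)
    else rlnorm(nReps, log(mean) - sdlog^2 / 2, sdlog)
  }
  rows <- lapply(names(baseProfile), function(a) {
    rbind(
      data.frame(analyte = a, sample = samples[1],
                 replicate = seq_len(nReps),
                 concentration = draw(baseProfile[[a]])),
      data.frame(analyte = a, sample = samples[2],
                 replicate = seq_len(nReps),
                 concentration = draw(scale * baseProfile[[a]])))
  })
  do.call(rbind, rows)
}

#' Default 33-analyte PAH concentration profile (synthetic)
#'
#' A synthetic stand-in for a measured passive-sampler extract profile:
#' the bundled 33-analyte panel with a pyrogenic-leaning composition whose
#' total is 190 uM at the 1 percent exposure scale and whose diagnostic
#' ratios sit at typical pyrogenic values (FLA/PYR ~ 1.1, PHE/ANT ~ 9,
#' RET/CHR ~ 0.5). Not measured data.
#'
#' @return named numeric of concentrations (uM) per analyte abbreviation.
#' @export
defaultPahProfile <- function() {
  panel <- pahPanel()
  conc <- c(
    NAP = 11.0, `1MNAP` = 5.2, `2MNAP` = 7.4, `12DMN` = 1.9, `16DMN` = 2.3,
    `26DMN` = 2.6, ACY = 2.1, ACE = 3.3, FLO = 6.0, DBT = 1.6,
    PHE = 27.0, ANT = 3.0, `2MPHE` = 4.2, `1MPHE` = 3.6, `36DMP` = 1.4,
    `2MANT` = 0.9, `9MANT` = 0.5, FLA = 26.4, PYR = 24.0, `1MPYR` = 1.8,
    RET = 5.0, BAA = 7.2, CHR = 10.0, `5MCHR` = 0.8, `6MCHR` = 0.7,
    BBF = 6.8, BKF = 4.4, BEP = 4.9, BAP = 6.1, PER = 1.7,
    IcdP = 2.7, DahA = 0.9, BghiP = 2.6)
  stopifnot(setequal(names(conc), panel$abbreviation))
  conc[panel$abbreviation]
}

#' The bundled 33-analyte PAH panel (synthetic reference table)
#'
#' Abbreviations and names for a representative 33-analyte quantitative
#' PAH panel (parent + alkylated PAHs typical of GC-MS water-quality
#' methods). Shipped as a plain-text table under \code{extdata}.
#'
#' @return data.frame with columns \code{abbreviation}, \code{name}.
#' @export
pahPanel <- function() {
  read.delim(system.file("extdata", "pah_panel_33_synthetic.tsv",
                         package = "mixturetox"))
}
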