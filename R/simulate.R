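# Seedable generator of synthetic hybrid-zone datasets: a two-pool
# gamete-union model producing heterozygote deficit (Wahlund effect) and
# inter-chromosomal LD, mixed rDNA arrays with unequal M/S copy numbers, a
# second-site null allele at the 2L RFLP, and noisy dual-peak traces.

#' Generative parameters of the synthetic hybrid zone
#'
#' Two parental gene pools (M-like and S-like) contribute gametes to each
#' individual.  With probability `1 - cross_mating` both gametes come from
#' the same pool (the M pool with probability `alpha`); otherwise the union
#' is panmictic and each gamete's pool of origin is drawn independently, so
#' that `cross_mating = 0` is a pure two-pool (Wahlund) mixture and
#' `cross_mating = 1` exact panmixia.  Loci are physically unlinked, so
#' alleles are drawn independently per locus given the pool of origin.  The defaults put
#' the diagnostic loci at fixed opposite alleles in the two pools
#' (frequency of the M allele 1 in the M pool, 0 in the S pool), mix the
#' pools equally, and set the cross-mating rate to 0.1 -- an order of
#' magnitude above the ~1% reported where the forms are reproductively
#' isolated, reflecting the elevated admixture this generator emulates.
#' The 2L second-site null allele defaults to its observed frequency of
#' 29.2%.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param loci Marker names (default `SINE-X`, `2L`, `3L`).
#' @param pool_freq_M,pool_freq_S Per-locus M-allele frequency in the M-like
#'   and S-like pool (recycled across loci).
#' @param alpha Proportion of gametes of M-pool origin.
#' @param cross_mating Probability that an individual is produced by
#'   panmictic (pool-independent) gamete union rather than within-pool
#'   mating.
#' @param null_allele_freq Frequency of the restriction-site-destroying
#'   second SNP at 2L.
#' @param seed Integer seed.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_individuals = 200,
                       loci = c("SINE-X", "2L", "3L"),
                       pool_freq_M = 1, pool_freq_S = 0,
                       alpha = 0.5, cross_mating = 0.1,
                       null_allele_freq = 0.292, seed = 1) {
  p <- list(n_individuals = as.integer(n_individuals), loci = loci,
            pool_freq_M = rep_len(pool_freq_M, length(loci)),
            pool_freq_S = rep_len(pool_freq_S, length(loci)),
            alpha = alpha, cross_mating = cross_mating,
            null_allele_freq = null_allele_freq, seed = as.integer(seed))
  probs <- c(p$pool_freq_M, p$pool_freq_S, alpha, cross_mating,
             null_allele_freq)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (p$n_individuals < 1) stop("n_individuals must be positive")
  names(p$pool_freq_M) <- names(p$pool_freq_S) <- loci
  structure(p, class = "sim_params")
}

#' Simulate a hybrid-zone population sample
#'
#' Draws genotypes under the two-pool gamete-union model of [sim_params()].
#' Pooling two differentiated gene pools produces the Wahlund heterozygote
#' deficit at every diagnostic locus and linkage disequilibrium between
#' unlinked loci; cross-mating moves the sample toward panmixia.
#'
#' @param p A [sim_params()] object.
#' @return A list with `records` (sample-record data frame consumable by
#'   [tabulate_locus()]/[tabulate_joint()] and [write_genotype_table()]) and
#'   `truth` (the generating parameters plus each individual's gamete pool
#'   origins and true per-gamete alleles).  Bit-identical for identical
#'   seeds.
#' @export
simulate_population <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  n <- p$n_individuals
  L <- length(p$loci)
  with_seed(p$seed, {
    # with probability 1 - c both gametes come from one pool (within-pool
    # mating); with probability c the union is panmictic, each gamete's pool
    # drawn independently, so c = 1 recovers exact panmixia and c = 0 the
    # pure two-pool (Wahlund) mixture
    panmictic <- stats::runif(n) < p$cross_mating
    pool1 <- ifelse(stats::runif(n) < p$alpha, "M", "S")
    pool2 <- ifelse(panmictic,
                    ifelse(stats::runif(n) < p$alpha, "M", "S"),
                    pool1)
    allele <- function(pool, locus) {
      f <- ifelse(pool == "M", p$pool_freq_M[locus], p$pool_freq_S[locus])
      ifelse(stats::runif(length(pool)) < f, "M", "S")
    }
    g1 <- sapply(p$loci, function(l) allele(pool1, l))
    g2 <- sapply(p$loci, function(l) allele(pool2, l))
    g1 <- matrix(g1, n, L); g2 <- matrix(g2, n, L)
    geno <- matrix(paste0(pmin(g1, g2), pmax(g1, g2)), n, L,
                   dimnames = list(NULL, p$loci))
    records <- data.frame(individual_id = sprintf("SIM-%04d", seq_len(n)),
                          site_code = "SIM", year = 0L,
                          stringsAsFactors = FALSE)
    for (l in p$loci) records[[l]] <- geno[, l]
    attr(records, "markers") <- p$loci
    list(records = records,
         truth = list(params = p, pool1 = pool1, pool2 = pool2,
                      gamete1 = g1, gamete2 = g2))
  })
}

#' Closed-form Wahlund inbreeding coefficient of the two-pool mixture
#'
#' Under a pure two-pool mixture (no cross-mating), pooling subpopulations
#' with M-allele frequencies p1 and p2 in proportions alpha : 1 - alpha
#' yields `F = alpha (1 - alpha) (p1 - p2)^2 / (pbar qbar)` with
#' `pbar = alpha p1 + (1 - alpha) p2` -- the expected heterozygote deficit
#' against which the simulator and the F_IS estimator are validated.
#'
#' @param p A [sim_params()] object with `cross_mating = 0`.
#' @param locus Locus name (one of `p$loci`).
#' @return The expected F, or `NA` when the pooled locus is fixed.
#' @examples
#' pp <- sim_params(pool_freq_M = 0.9, pool_freq_S = 0.1, cross_mating = 0)
#' expected_wahlund_fis(pp, "SINE-X")  # 0.64
#' @export
expected_wahlund_fis <- function(p, locus) {
  stopifnot(inherits(p, "sim_params"))
  if (p$cross_mating != 0)
    stop("closed form requires a pure two-pool mixture (cross_mating = 0)")
  p1 <- p$pool_freq_M[[locus]]
  p2 <- p$pool_freq_S[[locus]]
  pbar <- p$alpha * p1 + (1 - p$alpha) * p2
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  p$alpha * (1 - p$alpha) * (p1 - p2)^2 / (pbar * (1 - pbar))
}

#' Parameters of the synthetic rDNA array model
#'
#' The rDNA IGS region is a tandem array of hundreds of repeats; after
#' hybridization an individual can carry unequal numbers of M-type and
#' S-type repeats.  `mixture` gives, per X-chromosome ancestry class, the
#' Beta parameters of the S-copy proportion pi: parental MM individuals
#' concentrate near 0, SS near 1, and MS around 0.5 (so that balanced
#' arrays are more frequent in heterozygotes, as in F1 hybrids).  The
#' PCR-RFLP form call is driven by pi through the thresholds: below
#' `tau_low` the array types as pure M, above `tau_high` as pure S, and in
#' between as an M/S hybrid pattern.
#'
#' @param total_copies Nominal rDNA copies per individual (bookkeeping
#'   only; calls and scores depend on proportions).
#' @param mixture Named list of `c(shape1, shape2)` Beta parameters for the
#'   ancestry classes `MM`, `MS`, `SS`.
#' @param rflp_call_thresholds `c(tau_low, tau_high)` with
#'   `0 <= tau_low < tau_high <= 1`.
#' @param trace_noise_sd Standard deviation of the multiplicative log-normal
#'   noise applied to simulated peak heights.
#' @return An object of class `array_params`.
#' @export
array_params <- function(total_copies = 500,
                         mixture = list(MM = c(2, 38), MS = c(20, 20),
                                        SS = c(38, 2)),
                         rflp_call_thresholds = c(0.2, 0.8),
                         trace_noise_sd = 0.1) {
  th <- rflp_call_thresholds
  if (!(th[1] >= 0 && th[1] < th[2] && th[2] <= 1))
    stop("thresholds must satisfy 0 <= tau_low < tau_high <= 1")
  if (trace_noise_sd < 0) stop("trace_noise_sd must be non-negative")
  if (!all(c("MM", "MS", "SS") %in% names(mixture)))
    stop("mixture must name classes MM, MS, SS")
  structure(list(total_copies = total_copies, mixture = mixture,
                 rflp_call_thresholds = th,
                 trace_noise_sd = trace_noise_sd),
            class = "array_params")
}

#' Simulate mixed rDNA arrays and the resulting IGS form calls
#'
#' Draws each individual's S-copy proportion pi from the Beta mixture of its
#' X-chromosome ancestry class and derives the IGS PCR-RFLP call from the
#' thresholds.  The SINE-X genotype is the chromosomal ancestry itself,
#' independent of pi, so IGS-vs-SINE mismatches (both types of the mismatch
#' taxonomy) arise by construction whenever pi strays across a threshold.
#'
#' @param a An [array_params()] object.
#' @param ancestry Character vector of X-chromosome ancestry classes
#'   (`"MM"`, `"MS"`, `"SS"`), e.g. the SINE-X column of a simulated
#'   population.
#' @param seed Integer seed.
#' @return A data frame with `pi`, `igs_call` (`"M"`, `"MS"`, `"S"`) and
#'   `sine_x` (= `ancestry`).
#' @export
simulate_rdna_arrays <- function(a, ancestry, seed = 1) {
  stopifnot(inherits(a, "array_params"))
  if (!all(ancestry %in% .geno_levels))
    stop("ancestry classes must be 'MM', 'MS' or 'SS'")
  th <- a$rflp_call_thresholds
  with_seed(seed, {
    pi <- vapply(ancestry, function(cl) {
      pars <- a$mixture[[cl]]
      stats::rbeta(1, pars[1], pars[2])
    }, numeric(1), USE.NAMES = FALSE)
    igs <- ifelse(pi <= th[1], "M", ifelse(pi >= th[2], "S", "MS"))
    data.frame(pi = pi, igs_call = igs, sine_x = ancestry,
               stringsAsFactors = FALSE)
  })
}

#' Simulate dual-peak trace observations from known copy proportions
#'
#' Peak heights are proportional to the underlying copy fractions
#' (`h_S ~ pi`, `h_M ~ 1 - pi`), each multiplied by independent log-normal
#' noise; flanking reference heights are drawn from the same base intensity
#' and noise model.  This is the test harness for the CNP scoring pipeline:
#' with zero noise, [cnp_score()] of the resulting observation recovers pi
#' exactly.
#'
#' @param pi Numeric vector of S-copy proportions in `[0, 1]`.
#' @param a An [array_params()] object (supplies `trace_noise_sd`).
#' @param seed Integer seed.
#' @param site Diagnostic site label for the observations (581 or 690).
#' @param base_intensity Nominal trace intensity.
#' @param flank_n Flanking positions per side per channel.
#' @return A list of [peak_observation()] objects.
#' @export
simulate_traces <- function(pi, a, seed = 1, site = 581,
                            base_intensity = 1000, flank_n = 5) {
  stopifnot(inherits(a, "array_params"))
  if (any(pi < 0) || any(pi > 1)) stop("pi must lie in [0, 1]")
  sd <- a$trace_noise_sd
  noise <- function(k) if (sd > 0) stats::rlnorm(k, -sd^2 / 2, sd) else rep(1, k)
  with_seed(seed, {
    lapply(seq_along(pi), function(i) {
      peak_observation(
        individual_id = sprintf("TRC-%04d", i), site = site,
        h_M = max(base_intensity * (1 - pi[i]) * noise(1), 1e-12),
        h_S = max(base_intensity * pi[i] * noise(1), 0),
        flank_M = base_intensity * noise(2 * flank_n),
        flank_S = base_intensity * noise(2 * flank_n))
    })
  })
}

#' Apply the 2L second-site null allele to true genotypes
#'
#' The 2L diagnostic RFLP cleaves the M-form band; a second SNP inside the
#' recognition sequence destroys the site, so a chromosome carrying it
#' presents as uncleaved regardless of its M/S state.  Each chromosome
#' independently carries the disrupting SNP with probability `nu`.  The
#' observed call derives from the cleavage pattern: two cleaved bands ->
#' `MM`; one cleaved -> `MS` (which silently converts null-carrying MM
#' individuals into apparent heterozygotes); no cleaved band -> `SS` when
#' `nu = 0` (uncleaved can only mean S) but `U` (uncleaved-ambiguous) when
#' `nu > 0`, since an all-uncleaved pattern can then hide M alleles.
#'
#' @param genotypes Character vector of true 2L genotypes (`"MM"`, `"MS"`,
#'   `"SS"`).
#' @param nu Null-allele (second-site SNP) frequency in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `observed` (calls including `"U"`), `null_carrier`
#'   (0/1/2 disrupted chromosomes per individual) and `true` (the input).
#' @export
apply_null_allele <- function(genotypes, nu, seed = 1) {
  if (!all(genotypes %in% .geno_levels))
    stop("genotypes must be 'MM', 'MS' or 'SS'")
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]")
  n <- length(genotypes)
  with_seed(seed, {
    null1 <- stats::runif(n) < nu
    null2 <- stats::runif(n) < nu
    a1 <- substr(genotypes, 1, 1)
    a2 <- substr(genotypes, 2, 2)
    cleaved <- (a1 == "M" & !null1) + (a2 == "M" & !null2)
    observed <- ifelse(cleaved == 2, "MM",
                       ifelse(cleaved == 1, "MS",
                              if (nu > 0) "U" else "SS"))
    list(observed = observed, null_carrier = null1 + null2,
         true = genotypes)
  })
}
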