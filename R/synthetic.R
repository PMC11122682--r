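# Synthetic-data generators: replicated morph-count time series evolving
# under NFDS + drift + exogenous forcing, frequency-manipulation transplant
# experiments, and six-cluster structural-variant genotype data. These
# emulate the statistical structure of multi-decade field surveys of a
# striped / green / melanic colour-pattern polymorphism so the whole
# downstream pipeline can be exercised without field data.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulation configuration for morph-frequency time series
#'
#' Bundles and validates the parameters of the time-series generator. The
#' defaults emulate a compiled multi-decade field survey: 10 replicate
#' localities sampled for 14 consecutive years, roughly 70 individuals
#' scored per locality-year, locality-specific NFDS strength spanning
#' -0.70 to -0.32 (mean about -0.5), locality-specific equilibria tied to
#' the local host-plant composition, an effective population size of 110,
#' and a modest exogenous forcing (SD 0.15 on the logit-frequency scale)
#' standing in for gene flow and non-NFDS selection.
#'
#' @param n_localities Number of replicate localities.
#' @param years_per_locality Consecutive years sampled per locality.
#' @param D_true Per-locality NFDS parameter (recycled to `n_localities`);
#'   typically in (-1, 0).
#' @param p_eq_true Per-locality equilibrium stripe frequency in (0, 1).
#' @param Ne Effective population size (binomial drift on `2 * Ne` gene
#'   copies); `Ne >= 1`. Use a very large value to switch drift off.
#' @param forcing_sd SD of exogenous perturbations applied on the logit
#'   frequency scale each generation; `0` reproduces the pure NFDS +
#'   drift process.
#' @param sample_size Individuals scored per locality-year.
#' @param p0 Initial stripe frequency per locality; defaults to
#'   `p_eq_true`.
#' @param melanic_freq Time-constant frequency of the melanic morph
#'   (melanics do not fluctuate under NFDS in this system and are
#'   generated independently).
#' @param pct_adenostoma Percent of the thin-leaved host at each locality;
#'   defaults to `100 * p_eq_true` (equilibria in this system track host
#'   composition nearly linearly).
#' @param start_year First calendar year of each series.
#' @param seed Integer seed; identical `(config, seed)` gives identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_localities = 10,
                       years_per_locality = 14,
                       D_true = seq(-0.70, -0.32, length.out = n_localities),
                       p_eq_true = seq(0.25, 0.85, length.out = n_localities),
                       Ne = 110,
                       forcing_sd = 0.15,
                       sample_size = 70,
                       p0 = NULL,
                       melanic_freq = 0.05,
                       pct_adenostoma = NULL,
                       start_year = 2000,
                       seed = 1) {
  stopifnot(
    n_localities >= 1, years_per_locality >= 1,
    Ne >= 1, forcing_sd >= 0, sample_size >= 1,
    melanic_freq >= 0, melanic_freq < 1
  )
  D_true <- rep_len(D_true, n_localities)
  p_eq_true <- rep_len(p_eq_true, n_localities)
  if (any(p_eq_true <= 0 | p_eq_true >= 1)) {
    stop("`p_eq_true` must lie in the open interval (0, 1)", call. = FALSE)
  }
  p0 <- if (is.null(p0)) p_eq_true else rep_len(p0, n_localities)
  stopifnot(all(p0 >= 0 & p0 <= 1))
  if (is.null(pct_adenostoma)) pct_adenostoma <- 100 * p_eq_true
  pct_adenostoma <- rep_len(pct_adenostoma, n_localities)
  structure(
    list(
      n_localities = n_localities,
      years_per_locality = years_per_locality,
      D_true = D_true,
      p_eq_true = p_eq_true,
      Ne = Ne,
      forcing_sd = forcing_sd,
      sample_size = sample_size,
      p0 = p0,
      melanic_freq = melanic_freq,
      pct_adenostoma = pct_adenostoma,
      start_year = start_year,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_localities, "localities x",
      x$years_per_locality, "years;",
      "D in [", min(x$D_true), ",", max(x$D_true), "];",
      "Ne =", x$Ne, "; forcing_sd =", x$forcing_sd,
      "; n/yr =", x$sample_size, "\n")
  invisible(x)
}

# One latent stripe-frequency trajectory: deterministic NFDS pull, then
# logit-scale forcing, then binomial drift over 2*Ne gene copies.
sim_trajectory <- function(p0, D, p_eq, n_years, Ne, forcing_sd) {
  p <- numeric(n_years)
  p[1] <- p0
  eps <- 1e-9
  for (t in seq_len(n_years - 1)) {
    p_star <- p[t] + D * (p[t] - p_eq)
    p_star <- min(max(p_star, 0), 1)
    if (forcing_sd > 0) {
      z <- logit(min(max(p_star, eps), 1 - eps)) + stats::rnorm(1, 0, forcing_sd)
      p_star <- inv_logit(z)
    }
    p[t + 1] <- stats::rbinom(1, 2 * Ne, p_star) / (2 * Ne)
  }
  p
}

#' Generate replicated morph-count time series
#'
#' For each locality the latent stripe frequency evolves by the linear
#' NFDS recursion `p* = p + D * (p - p_eq)`, receives Normal(0,
#' `forcing_sd`) noise on the logit scale, and is then resampled as
#' `Binomial(2 * Ne, p*) / (2 * Ne)` (genetic drift). Observed counts are
#' a multinomial draw of `sample_size` individuals: melanics at the
#' time-constant `melanic_freq`, the remainder split striped versus green
#' at the latent stripe frequency. Records are emitted per host plant
#' (individuals assigned to hosts by the locality's host composition;
#' the stripe frequency is common to the two hosts within a locality).
#'
#' Trajectories absorbed at 0 or 1 by drift are returned as-is and
#' flagged in the truth table.
#'
#' @param config A [sim_config()].
#' @return A list of class `morph_sim` with elements `counts` (tibble:
#'   `locality`, `year`, `host`, `n_striped`, `n_green`, `n_melanic`) and
#'   `truth` (tibble: `locality`, `year`, `p_true`, `absorbed`), plus the
#'   config as an attribute.
#' @examples
#' sim <- sim_morph_series(sim_config(n_localities = 2, seed = 7))
#' head(sim$counts)
#' @export
sim_morph_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  loc_ids <- sprintf("L%02d", seq_len(config$n_localities))
  years <- config$start_year + seq_len(config$years_per_locality) - 1L

  truth <- vector("list", config$n_localities)
  counts <- vector("list", config$n_localities)
  for (j in seq_len(config$n_localities)) {
    p <- sim_trajectory(
      config$p0[j], config$D_true[j], config$p_eq_true[j],
      config$years_per_locality, config$Ne, config$forcing_sd
    )
    truth[[j]] <- tibble::tibble(
      locality = loc_ids[j], year = years, p_true = p,
      absorbed = any(p == 0 | p == 1)
    )
    n_mel <- stats::rbinom(length(p), config$sample_size, config$melanic_freq)
    n_str <- stats::rbinom(length(p), config$sample_size - n_mel, p)
    n_grn <- config$sample_size - n_mel - n_str
    # assign individuals to hosts by the locality's host composition
    share_ad <- config$pct_adenostoma[j] / 100
    str_ad <- stats::rbinom(length(p), n_str, share_ad)
    grn_ad <- stats::rbinom(length(p), n_grn, share_ad)
    mel_ad <- stats::rbinom(length(p), n_mel, share_ad)
    counts[[j]] <- dplyr::bind_rows(
      tibble::tibble(
        locality = loc_ids[j], year = years, host = "Adenostoma",
        n_striped = str_ad, n_green = grn_ad, n_melanic = mel_ad
      ),
      tibble::tibble(
        locality = loc_ids[j], year = years, host = "Ceanothus",
        n_striped = n_str - str_ad, n_green = n_grn - grn_ad,
        n_melanic = n_mel - mel_ad
      )
    )
  }
  out <- list(
    counts = dplyr::arrange(dplyr::bind_rows(counts),
                            .data$locality, .data$year, .data$host),
    truth = dplyr::bind_rows(truth)
  )
  attr(out, "config") <- config
  class(out) <- "morph_sim"
  out
}

#' @export
print.morph_sim <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<morph_sim>", cfg$n_localities, "localities,",
      nrow(x$counts), "count records\n")
  invisible(x)
}

#' Parametric relative-fitness functions for experiment generation
#'
#' `fitness_linear()` gives relative fitness `w(p) = a + b * p` of the
#' striped morph as a function of the released stripe frequency `p`;
#' `fitness_sigmoidal()` gives a four-parameter logistic
#' `w(p) = lower + (upper - lower) / (1 + exp(-steepness * (p - midpoint)))`
#' (step-like NFDS when `steepness` is large and `upper < lower` is
#' encoded by a negative `steepness`).
#'
#' @param a,b Linear intercept and slope.
#' @param lower,upper,midpoint,steepness Four-parameter logistic
#'   parameters.
#' @return A function of `p` returning relative fitness, tagged with the
#'   form and parameters.
#' @export
fitness_linear <- function(a = 1.6, b = -0.8) {
  f <- function(p) a + b * p
  attr(f, "form") <- "linear"
  attr(f, "params") <- c(a = a, b = b)
  f
}

#' @rdname fitness_linear
#' @export
fitness_sigmoidal <- function(lower = 0.6, upper = 1.6, midpoint = 0.5,
                              steepness = -12) {
  f <- function(p) lower + (upper - lower) / (1 + exp(-steepness * (p - midpoint)))
  attr(f, "form") <- "sigmoidal"
  attr(f, "params") <- c(lower = lower, upper = upper,
                         midpoint = midpoint, steepness = steepness)
  f
}

#' Generate a frequency-manipulation transplant experiment
#'
#' Releases `n_per_bush` individuals on each experimental bush with the
#' stripe frequency set by `release_freqs` (the default grid, 0 to 1 in
#' 5% steps over 21 bushes, matches a classical 21-treatment design of 20
#' insects per bush). Recaptures are binomial per morph per bush:
#' the green (unstriped) recapture probability is `base_recapture`
#' (optionally with bush-level logit noise `bush_sd`), and the striped
#' probability is `fitness(p) * base_recapture`, clamped to
#' \[0.01, 0.99\]. Released counts use round-half-to-even to convert grid
#' frequencies into integers.
#'
#' @param release_freqs Release stripe frequencies, each representable as
#'   an integer count out of `n_per_bush`.
#' @param n_per_bush Individuals released per bush.
#' @param fitness A relative-fitness function, e.g. [fitness_linear()].
#' @param base_recapture Recapture probability of the green morph.
#' @param bush_sd SD of a bush-level perturbation of the baseline
#'   recapture probability on the logit scale (0 = none).
#' @param seed Integer seed.
#' @return Tibble with columns `bush`, `block`, `release_freq`,
#'   `released_striped`, `released_other`, `recaptured_striped`,
#'   `recaptured_other`.
#' @export
sim_transplant_experiment <- function(release_freqs = seq(0, 1, by = 0.05),
                                      n_per_bush = 20,
                                      fitness = fitness_linear(),
                                      base_recapture = 0.5,
                                      bush_sd = 0,
                                      seed = 1) {
  stopifnot(all(release_freqs >= 0 & release_freqs <= 1), n_per_bush >= 1)
  rel_striped <- round(release_freqs * n_per_bush)  # round-half-to-even
  if (any(abs(rel_striped - release_freqs * n_per_bush) > 1e-6)) {
    warning("some release frequencies are not integer counts out of ",
            n_per_bush, "; rounded half-to-even", call. = FALSE)
  }
  withr::local_seed(seed)
  n_bush <- length(release_freqs)
  base <- if (bush_sd > 0) {
    inv_logit(logit(base_recapture) + stats::rnorm(n_bush, 0, bush_sd))
  } else {
    rep(base_recapture, n_bush)
  }
  w <- fitness(release_freqs)
  q_s <- pmin(pmax(w * base, 0.01), 0.99)
  q_g <- pmin(pmax(base, 0.01), 0.99)
  if (any(w * base < 0 | w * base > 1)) {
    warning("fitness parameters yield recapture probabilities outside (0, 1); ",
            "clamped to [0.01, 0.99]", call. = FALSE)
  }
  rel_other <- n_per_bush - rel_striped
  tibble::tibble(
    bush = sprintf("B%02d", seq_len(n_bush)),
    block = NA_character_,
    release_freq = release_freqs,
    released_striped = as.integer(rel_striped),
    released_other = as.integer(rel_other),
    recaptured_striped = stats::rbinom(n_bush, rel_striped, q_s),
    recaptured_other = stats::rbinom(n_bush, rel_other, q_g)
  )
}

#' Generate a blocked striped-versus-melanic transplant experiment
#'
#' Each block releases `n_per_morph` striped and `n_per_morph` melanic
#' individuals on one bush (default design: 8 blocks of 10 + 10).
#' Recapture is logistic: `logit(q) = base_logit + block effect + beta *
#' striped`, so `beta` is the log-odds fitness advantage of the striped
#' morph.
#'
#' @param n_blocks Number of blocks.
#' @param n_per_morph Individuals released per morph per block.
#' @param beta Log-odds recapture advantage of striped over melanic.
#' @param base_logit Baseline (melanic) recapture log-odds.
#' @param block_sd SD of Normal block effects on the logit scale.
#' @param seed Integer seed.
#' @return Tibble with columns `block`, `released_striped`,
#'   `released_melanic`, `recaptured_striped`, `recaptured_melanic`.
#' @export
sim_advantage_experiment <- function(n_blocks = 8, n_per_morph = 10,
                                     beta = 1.49, base_logit = -1,
                                     block_sd = 0.5, seed = 1) {
  stopifnot(n_blocks >= 1, n_per_morph >= 1)
  withr::local_seed(seed)
  u <- stats::rnorm(n_blocks, 0, block_sd)
  q_mel <- inv_logit(base_logit + u)
  q_str <- inv_logit(base_logit + u + beta)
  tibble::tibble(
    block = sprintf("K%d", seq_len(n_blocks)),
    released_striped = n_per_morph,
    released_melanic = n_per_morph,
    recaptured_striped = stats::rbinom(n_blocks, n_per_morph, q_str),
    recaptured_melanic = stats::rbinom(n_blocks, n_per_morph, q_mel)
  )
}

#' The six structural-variant genotype classes
#'
#' Unordered pairs over the three structural haplotype alleles
#' (green, striped, melanic).
#' @return Character vector of the six class labels.
#' @export
genotype_cluster_levels <- function() {
  c("green/green", "striped/striped", "melanic/melanic",
    "green/striped", "green/melanic", "striped/melanic")
}

#' Generate six-cluster structural-variant genotype data
#'
#' Individuals are drawn multinomially over the six genotype classes. If
#' `n_snps` is given, a 0/1/2 SNP dosage matrix is also generated in
#' which each structural haplotype allele carries its own SNP
#' allele-frequency profile and an individual's dosage at a SNP is the sum
#' of two Bernoulli draws, one per haplotype. With well-separated
#' profiles the six classes form six linearly separable clusters in the
#' top two principal components (three homozygote corners and three
#' heterozygote midpoints).
#'
#' @param n Number of individuals.
#' @param cluster_probs Probabilities of the six genotype classes, in the
#'   order of [genotype_cluster_levels()]; non-negative, summing to 1.
#' @param seed Integer seed.
#' @param n_snps Optional number of SNPs to simulate.
#' @param separation In (0, 0.5): haplotype allele frequencies are drawn
#'   from `{separation, 1 - separation}`; smaller values separate the
#'   clusters more strongly.
#' @return A list of class `genotype_sim`: `individuals` (tibble:
#'   `individual`, `genotype_cluster`) and `snps` (dosage matrix or
#'   `NULL`).
#' @export
sim_genotypes <- function(n, cluster_probs, seed = 1, n_snps = NULL,
                          separation = 0.05) {
  stopifnot(length(cluster_probs) == 6, n >= 1)
  if (any(cluster_probs < 0)) {
    stop("`cluster_probs` must be non-negative", call. = FALSE)
  }
  if (abs(sum(cluster_probs) - 1) > 1e-6) {
    stop("`cluster_probs` must sum to 1", call. = FALSE)
  }
  withr::local_seed(seed)
  lev <- genotype_cluster_levels()
  cls <- sample(lev, n, replace = TRUE, prob = cluster_probs)
  individuals <- tibble::tibble(
    individual = sprintf("ind%04d", seq_len(n)),
    genotype_cluster = cls
  )
  snps <- NULL
  if (!is.null(n_snps)) {
    stopifnot(n_snps >= 1, separation > 0, separation < 0.5)
    hap_of <- strsplit(lev, "/", fixed = TRUE)
    names(hap_of) <- lev
    # per-haplotype SNP allele-frequency profiles, near-fixed for contrast
    prof <- matrix(
      sample(c(separation, 1 - separation), 3 * n_snps, replace = TRUE),
      nrow = 3, dimnames = list(c("green", "striped", "melanic"), NULL)
    )
    snps <- matrix(0L, nrow = n, ncol = n_snps,
                   dimnames = list(individuals$individual,
                                   sprintf("snp%04d", seq_len(n_snps))))
    for (i in seq_len(n)) {
      h <- hap_of[[cls[i]]]
      snps[i, ] <- stats::rbinom(n_snps, 1, prof[h[1], ]) +
        stats::rbinom(n_snps, 1, prof[h[2], ])
    }
  }
  structure(list(individuals = individuals, snps = snps),
            class = "genotype_sim")
}
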