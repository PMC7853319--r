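#' Bayes-factor model comparison from log marginal likelihoods
#'
#' Given an ordered list of log marginal likelihoods (e.g. Bezier-approximated
#' values from structured-coalescent migration models), computes the log Bayes
#' factor of each model against its predecessor,
#' `LBF_x = 2 * (lnmL_x - lnmL_{x-1})`, and posterior model probabilities
#' `exp(lnmL_i - logsumexp(lnmL))` under equal model priors, evaluated stably
#' in log space. Only the arithmetic on printed lnmL values is performed here;
#' estimating the marginal likelihoods themselves is upstream of this package.
#'
#' @param lnml numeric vector of log marginal likelihoods, in model order.
#' @param labels optional model labels.
#' @param m_pattern optional character vector describing each model's
#'   migration-parameter pattern.
#' @return A `model_comparison` data frame: `model`, `m_pattern`, `lnmL`,
#'   `LBF` (NA for the first model), `probability` (sums to 1).
#' @export
lbf_table <- function(lnml, labels = NULL, m_pattern = NULL) {
  lnml <- as.numeric(lnml)
  if (length(lnml) < 2L) stop("need at least two models")
  if (any(!is.finite(lnml))) stop("non-finite log marginal likelihood")
  if (is.null(labels)) labels <- as.character(seq_along(lnml))
  lse <- max(lnml) + log(sum(exp(lnml - max(lnml))))
  out <- data.frame(model = labels,
                    m_pattern = if (is.null(m_pattern)) NA_character_ else m_pattern,
                    lnmL = lnml,
                    LBF = c(NA, 2 * diff(lnml)),
                    probability = exp(lnml - lse),
                    stringsAsFactors = FALSE)
  structure(out, class = c("model_comparison", "data.frame"))
}

#' Ratio of split time to effective population size
#'
#' Converts a mutation-scaled population size theta into an effective size
#' `Ne = theta / (x * mu)` (with `x` the inheritance scalar: 4 for diploid
#' nuclear loci, 1 for a haploid maternally inherited locus, i.e. an
#' effective count of Ne/2 breeding females) and a split time in Ma into
#' generations, returning `t / Ne` - the quantity that governs the
#' probability that lineage sorting is complete.
#'
#' @param theta mutation-scaled population size.
#' @param mu mutation rate per site per generation.
#' @param split_ma split time in Ma.
#' @param generation_years generation time in years.
#' @param x inheritance scalar (1, 2 or 4).
#' @return A list: `Ne`, `t_generations`, `ratio`.
#' @export
t_over_ne <- function(theta, mu, split_ma, generation_years, x = 4) {
  stopifnot(theta > 0, generation_years > 0, split_ma >= 0, x %in% c(1, 2, 4))
  if (mu <= 0) stop("mutation rate must be positive")
  ne <- theta / (x * mu)
  t_gen <- split_ma * 1e6 / generation_years
  list(Ne = ne, t_generations = t_gen, ratio = t_gen / ne)
}

#' Coalescent probability of reciprocal monophyly
#'
#' Simulates a clean two-population split: `samples_per_species` gene copies
#' per species coalesce within their own population for `t_over_ne` (in units
#' of the diploid effective size Ne, converted onto each locus's own
#' coalescent timescale) and then merge into a panmictic ancestral
#' population. A replicate succeeds if, at every locus, both species' samples
#' are reciprocally monophyletic. The locus timescale is `x * Ne / 2` gene
#' copies (x = 4: diploid nuclear, 2Ne copies; x = 1: haploid maternal, Ne/2
#' copies), so a maternally inherited locus experiences `2 * t_over_ne`
#' coalescent units of isolation and a nuclear locus `t_over_ne / 2`. This
#' calibration reproduces the classical 0.95-probability thresholds
#' (t/Ne >= 2.2 for one mitochondrial locus; >= 11.8 jointly for five nuclear
#' loci) within Monte-Carlo error.
#'
#' @param t_over_ne split time over diploid Ne, in generations/Ne.
#' @param n_loci independent loci that must all be monophyletic.
#' @param samples_per_species gene copies sampled per species.
#' @param reps coalescent replicates (>= 1000; fewer gives a wide CI).
#' @param x inheritance scalar (1 = haploid maternal, 4 = diploid nuclear).
#' @param seed optional stream seed.
#' @return A list: `prob`, `se` (binomial Monte-Carlo error), `reps`, `tau`
#'   (the per-locus split time in coalescent units).
#' @export
monophyly_prob <- function(t_over_ne, n_loci = 1, samples_per_species = 10,
                           reps = 10000, x = 4, seed = NULL) {
  stopifnot(t_over_ne >= 0, n_loci >= 1, samples_per_species >= 1,
            x %in% c(1, 2, 4))
  if (reps < 1000) warning("fewer than 1000 replicates: Monte-Carlo CI is wide")
  tau <- 2 * t_over_ne / x
  succ <- with_seed(seed,
    recip_mono_cpp(tau, as.integer(samples_per_species), as.integer(n_loci),
                   as.integer(reps)))
  p <- succ / reps
  list(prob = p, se = sqrt(p * (1 - p) / reps), reps = as.integer(reps),
       tau = tau)
}

#' Smallest t/Ne on a grid reaching a target monophyly probability
#'
#' @param grid increasing grid of `t_over_ne` values.
#' @param target probability to reach (default 0.95).
#' @param ... passed to [monophyly_prob()] (`n_loci`, `x`, `reps`, ...).
#' @param seed optional stream seed.
#' @return A list: `threshold` (smallest grid value with prob >= target, NA
#'   if never reached) and `curve` (data frame of `t_over_ne`, `prob`, `se`).
#' @export
monophyly_threshold <- function(grid, target = 0.95, seed = NULL, ...) {
  stopifnot(all(diff(grid) > 0))
  probs <- numeric(length(grid))
  ses <- numeric(length(grid))
  for (i in seq_along(grid)) {
    m <- monophyly_prob(grid[i], seed = fan_seed(seed, i), ...)
    probs[i] <- m$prob
    ses[i] <- m$se
  }
  hit <- which(probs >= target)
  list(threshold = if (length(hit)) grid[min(hit)] else NA_real_,
       curve = data.frame(t_over_ne = grid, prob = probs, se = ses))
}
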