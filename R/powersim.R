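#' Power simulation for hybrid-category assignment
#'
#' Simulates known-class individuals from an allele-frequency panel,
#' classifies them with the six-category Bayesian model using simulated pure
#' references, and tabulates per class, over a grid of critical posterior
#' thresholds:
#' efficiency (P(true class is called as that class)), accuracy
#' (P(an individual called as the class truly is)), power = efficiency x
#' accuracy, Type I error (P(a non-member is called as the class, non-members
#' pooled)) and Type II error (1 - efficiency). These are the conventions of
#' the standard hybrid-detection power workflow; they are stated here because
#' they are rarely written out.
#'
#' Two classification designs are available. `design = "joint"` (default)
#' classifies each replicate's full six-class mixture in a single assignment
#' run, so the mixing proportions see an equal-class sample; this is the
#' design under which the F2-efficiency enumeration oracle holds. With only a
#' handful of loci it places a hard ceiling on F1 power at strict thresholds:
#' every F2 or backcross pedigree produces an F1-indistinguishable multilocus
#' heterozygote with probability `(1/2)^L`, and the per-locus likelihood
#' ratio of those categories against F1 is never below 1/2, so under
#' near-uniform mixing the F1 posterior cannot exceed roughly
#' `1/(1 + 3 * 2^-L)` (0.84 at L = 4) - just below a 0.85 calling threshold.
#' `design = "per_class"` classifies each class's individuals in their own
#' assignment run (references shared), letting the mixing proportions adapt
#' to the focal class as they do when a field sample dominated by one class
#' is analysed; this reproduces high pure/F1 power but inflates F2 and
#' backcross power relative to the joint design. See the package vignette.
#'
#' @param panel two-species `allele_panel` (see [make_panel()] for the
#'   diagnosticity parameterisation used for marker panels).
#' @param n_per_class simulated individuals per class per replicate.
#' @param thresholds grid of critical posterior thresholds in (0.5, 1].
#' @param reps simulated datasets.
#' @param n_refs pure reference individuals per species (classifier priors).
#' @param design `"joint"` or `"per_class"` (see Details).
#' @param method,pi,burnin,sweeps passed to [fit_newhybrids()].
#' @param seed optional stream seed.
#' @return A `power_report` data frame: `class`, `threshold`, `efficiency`,
#'   `accuracy`, `power`, `type1`, `type2` (means over replicates) and the
#'   corresponding `sd_*` columns, with attribute `settings`.
#' @export
run_power_sim <- function(panel, n_per_class = 200,
                          thresholds = seq(0.5, 0.95, by = 0.05), reps = 3,
                          n_refs = 100, design = c("joint", "per_class"),
                          method = "mcmc", pi = "sample",
                          burnin = 1000, sweeps = 50000, seed = NULL) {
  stopifnot(inherits(panel, "allele_panel"), n_per_class >= 1, reps >= 1)
  design <- match.arg(design)
  if (any(thresholds <= 0.5 | thresholds > 1))
    stop("thresholds must lie in (0.5, 1]")
  classes <- rownames(hybrid_categories())
  degenerate <- all(vapply(panel, function(f)
    max(abs(f[1, ] - f[2, ])) < 1e-9, TRUE))
  if (degenerate)
    warning("panel has no frequency differences between species; rates will be near chance")
  acc <- list()
  for (r in seq_len(reps)) {
    sim <- lapply(classes, function(cl)
      simulate_cross(panel, cl, n_per_class, seed = fan_seed(seed, 100L * r + match(cl, classes))))
    truth <- rep(classes, each = n_per_class)
    refs_a <- simulate_cross(panel, "pureA", n_refs, seed = fan_seed(seed, 100L * r + 50L))
    refs_b <- simulate_cross(panel, "pureB", n_refs, seed = fan_seed(seed, 100L * r + 51L))
    if (design == "joint") {
      g <- do.call(rbind.genotype_matrix, sim)
      post <- fit_newhybrids(g, refs_a, refs_b, burnin = burnin, sweeps = sweeps,
                             pi = pi, method = method,
                             seed = fan_seed(seed, 100L * r + 99L))
    } else {
      post <- do.call(rbind, lapply(seq_along(classes), function(i)
        unclass(fit_newhybrids(sim[[i]], refs_a, refs_b, burnin = burnin,
                               sweeps = sweeps, pi = pi, method = method,
                               seed = fan_seed(seed, 100L * r + 90L + i)))))
    }
    for (th in thresholds) {
      calls <- assign_threshold(post, th)$call
      for (cl in classes) {
        is_cl <- truth == cl
        det <- calls == cl
        eff <- mean(det[is_cl])
        accv <- if (sum(det) > 0) sum(det & is_cl) / sum(det) else NA_real_
        acc[[length(acc) + 1L]] <- data.frame(
          rep = r, class = cl, threshold = th, efficiency = eff,
          accuracy = accv, power = eff * ifelse(is.na(accv), 0, accv),
          type1 = mean(det[!is_cl]), type2 = 1 - eff)
      }
    }
  }
  long <- do.call(rbind, acc)
  agg <- stats::aggregate(long[c("efficiency", "accuracy", "power", "type1", "type2")],
                          by = long[c("class", "threshold")],
                          FUN = function(v) mean(v, na.rm = TRUE))
  sds <- stats::aggregate(long[c("efficiency", "accuracy", "power", "type1", "type2")],
                          by = long[c("class", "threshold")],
                          FUN = function(v) if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else NA_real_)
  names(sds)[-(1:2)] <- paste0("sd_", names(sds)[-(1:2)])
  out <- merge(agg, sds, by = c("class", "threshold"))
  out <- out[order(match(out$class, classes), out$threshold), ]
  rownames(out) <- NULL
  structure(out, class = c("power_report", "data.frame"),
            settings = list(n_per_class = n_per_class, reps = reps,
                            n_refs = n_refs, design = design,
                            method = method, pi = pi,
                            burnin = burnin, sweeps = sweeps, seed = seed,
                            panel = panel, degenerate = degenerate),
            replicates = long)
}

#' Backcross contamination check for pure-sample filtering
#'
#' Fits a three-cluster admixture model to pooled simulated classes (pure
#' individuals of all three species plus F1, F2 and both backcross directions
#' of a designated species pair) and reports, per class, the fraction of
#' individuals whose maximum Q reaches the pure-calling threshold (such
#' individuals would contaminate a "pure" sample) and the fraction whose
#' minor-cluster Q values all fall below the hybrid-filter threshold (such
#' individuals would evade a "Q > 0.10 in more than one cluster" hybrid
#' filter).
#'
#' @param panel three-species `allele_panel`.
#' @param pair two species labels (the simulated cross).
#' @param n_per_class individuals per class per replicate.
#' @param reps replicate simulated datasets; Q values are averaged over
#'   replicate model fits as in the replicate-averaging convention.
#' @param pure_threshold,hybrid_threshold filtering thresholds.
#' @param burnin,sweeps admixture run lengths.
#' @param seed optional stream seed.
#' @return A `contamination_report` data frame: `class`, `n`, `mean_max_q`,
#'   `frac_pure_pass` and `frac_filter_evade`.
#' @export
contamination_check <- function(panel, pair = panel_species(panel)[1:2],
                                n_per_class = 100, reps = 3,
                                pure_threshold = 0.90, hybrid_threshold = 0.10,
                                burnin = 1000, sweeps = 20000, seed = NULL) {
  sp <- panel_species(panel)
  if (length(sp) < 3L) stop("panel must cover three species")
  stopifnot(all(pair %in% sp))
  third <- setdiff(sp, pair)[1]
  sub <- subset_panel(panel, pair)
  classes <- c("pureA", "pureB", "F1", "F2", "bcA", "bcB")
  sim <- lapply(classes, function(cl)
    simulate_cross(sub, cl, n_per_class, seed = fan_seed(seed, match(cl, classes))))
  pure3 <- simulate_cross(subset_panel(panel, c(third, pair[1])), "pureA",
                          n_per_class, seed = fan_seed(seed, 7L))
  g <- do.call(rbind.genotype_matrix, c(sim, list(pure3)))
  truth <- c(rep(classes, each = n_per_class), rep("pureC", n_per_class))
  runs <- lapply(seq_len(reps), function(r)
    fit_admixture(g, K = 3, burnin = burnin, sweeps = sweeps,
                  seed = fan_seed(seed, 10L + r)))
  Q <- align_replicates(runs)
  maxq <- apply(Q, 1, max)
  minorq <- apply(Q, 1, function(q) sort(q, decreasing = TRUE)[2])
  out <- do.call(rbind, lapply(unique(truth), function(cl) {
    i <- truth == cl
    data.frame(class = cl, n = sum(i), mean_max_q = mean(maxq[i]),
               frac_pure_pass = mean(maxq[i] >= pure_threshold),
               frac_filter_evade = mean(minorq[i] < hybrid_threshold),
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("contamination_report", "data.frame"),
            settings = list(pair = pair, pure_threshold = pure_threshold,
                            hybrid_threshold = hybrid_threshold, seed = seed))
}
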