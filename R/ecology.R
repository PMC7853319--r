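#' Per-site relative abundance from survey counts
#'
#' Converts site-level counts (species x phase within sites nested in
#' localities) into per-site species proportions and per-locality means.
#' Empty sites are excluded with a warning.
#'
#' @param counts data frame with columns `locality`, `site`, `species`,
#'   `count` (an optional `phase` column is summed over unless `phases`
#'   restricts it, e.g. `c("IP", "TP")` for adults only).
#' @param phases optional subset of phases to keep before summing.
#' @return A list: `site` (data frame of per-site proportions) and
#'   `locality` (per-locality mean and sd of each species' proportion).
#' @export
relative_abundance <- function(counts, phases = NULL) {
  stopifnot(all(c("locality", "site", "species", "count") %in% names(counts)))
  if (!is.null(phases)) {
    if (!"phase" %in% names(counts)) stop("no phase column to filter")
    counts <- counts[counts$phase %in% phases, ]
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop("counts must be non-negative integers")
  tot <- stats::aggregate(count ~ locality + site + species, counts, sum)
  site_tot <- stats::aggregate(count ~ locality + site, tot, sum)
  names(site_tot)[3] <- "site_total"
  empty <- site_tot$site_total == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty site(s)")
    site_tot <- site_tot[!empty, ]
  }
  m <- merge(tot, site_tot, by = c("locality", "site"))
  m$proportion <- m$count / m$site_total
  loc <- merge(
    stats::aggregate(proportion ~ locality + species, m, mean),
    stats::aggregate(proportion ~ locality + species, m,
                     function(v) if (length(v) > 1) stats::sd(v) else NA_real_),
    by = c("locality", "species"))
  names(loc)[3:4] <- c("mean_proportion", "sd_proportion")
  list(site = m[order(m$locality, m$site, m$species), ],
       locality = loc[order(loc$locality, loc$species), ])
}

#' One-way ANOVA with Tukey HSD on site-level proportions
#'
#' Fixed-effects one-way ANOVA of a proportion (or any response) across
#' groups, with Tukey honest-significant-difference pairwise comparisons via
#' the studentized-range distribution. Proportions are analysed untransformed
#' by default; `transform = "asin_sqrt"` applies the arcsine-square-root
#' variance-stabilising transform for sensitivity analysis.
#'
#' @param values numeric response (e.g. per-site proportions of one species).
#' @param groups grouping factor (e.g. locality).
#' @param transform `"none"` or `"asin_sqrt"`.
#' @return A list: `F`, `df` (numerator, denominator), `p`, `tukey` (data
#'   frame of pairwise differences and adjusted p-values), `anova` (the aov
#'   fit).
#' @export
anova_tukey <- function(values, groups, transform = c("none", "asin_sqrt")) {
  transform <- match.arg(transform)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("need at least two observations per group")
  y <- if (transform == "asin_sqrt") asin(sqrt(values)) else values
  if (all(tapply(y, groups, stats::var) == 0))
    stop("zero within-group variance everywhere; F undefined")
  fit <- stats::aov(y ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p = s[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       anova = fit)
}

#' Estimated abundance of hybrid varieties
#'
#' Scales each hybrid variety's frequency among genotyped individuals by the
#' total adult count of the locality: estimated abundance = adult count x
#' genetic-sample frequency. A locality with counts but no genotyped samples
#' is omitted with a warning.
#'
#' @param adult_counts data frame with columns `locality`, `adults`.
#' @param genetic_calls data frame with columns `locality`, `variety` (one
#'   row per genotyped individual; non-hybrid individuals should carry their
#'   species label so that frequencies are relative to the full genotyped
#'   sample).
#' @param varieties which variety labels to report (default: all present).
#' @return A `variety_abundance` data frame: `locality`, `variety`,
#'   `frequency`, `adults`, `estimated_abundance`.
#' @export
variety_abundance <- function(adult_counts, genetic_calls, varieties = NULL) {
  stopifnot(all(c("locality", "adults") %in% names(adult_counts)),
            all(c("locality", "variety") %in% names(genetic_calls)))
  if (is.null(varieties)) varieties <- sort(unique(genetic_calls$variety))
  rows <- list()
  for (i in seq_len(nrow(adult_counts))) {
    loc <- adult_counts$locality[i]
    calls <- genetic_calls$variety[genetic_calls$locality == loc]
    if (length(calls) == 0L) {
      warning("locality ", loc, " has counts but no genotyped samples; omitted")
      next
    }
    for (v in varieties) {
      f <- mean(calls == v)
      rows[[length(rows) + 1L]] <- data.frame(
        locality = loc, variety = v, frequency = f,
        adults = adult_counts$adults[i],
        estimated_abundance = adult_counts$adults[i] * f,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("variety_abundance", "data.frame"))
}

# round half up to integer percentages, matching printed-table conventions
round_half_up <- function(x) floor(x + 0.5)

#' Reproductive summaries from gonad tables
#'
#' From per-species counts of sexed and sexually active individuals by colour
#' phase (IP = initial phase, TP = terminal phase), computes the percentage
#' of the sample that was sexually mature,
#' `%SM = 100 * (sexed males + sexed females) / n`, and the percentage of
#' active individuals within each phase x sex cell,
#' `100 * active / sexed`. Percentages are rounded half-up to integers to
#' match printed tables; a cell with zero sexed individuals has an undefined
#' activity percentage, reported as `NA` rather than 0.
#'
#' @param tab data frame with columns `species`, `n`, `male_IP`, `male_TP`,
#'   `female_IP`, `female_TP`, `active_male_IP`, `active_male_TP`,
#'   `active_female_IP`, `active_female_TP`.
#' @return A `gonad_summary` data frame with `pct_sm` and the four
#'   `pct_active_*` columns per species.
#' @export
gonad_summary <- function(tab) {
  need <- c("species", "n", "male_IP", "male_TP", "female_IP", "female_TP",
            "active_male_IP", "active_male_TP", "active_female_IP",
            "active_female_TP")
  stopifnot(all(need %in% names(tab)))
  sexed <- tab$male_IP + tab$male_TP + tab$female_IP + tab$female_TP
  if (any(sexed > tab$n)) stop("sexed totals exceed n")
  for (cell in c("male_IP", "male_TP", "female_IP", "female_TP"))
    if (any(tab[[paste0("active_", cell)]] > tab[[cell]]))
      stop("active counts exceed sexed counts in ", cell)
  pct_act <- function(cell) {
    act <- tab[[paste0("active_", cell)]]
    ifelse(tab[[cell]] > 0, round_half_up(100 * act / tab[[cell]]), NA_real_)
  }
  structure(data.frame(species = tab$species,
                       n = tab$n, n_sexed = sexed,
                       pct_sm = round_half_up(100 * sexed / tab$n),
                       pct_active_male_IP = pct_act("male_IP"),
                       pct_active_male_TP = pct_act("male_TP"),
                       pct_active_female_IP = pct_act("female_IP"),
                       pct_active_female_TP = pct_act("female_TP"),
                       stringsAsFactors = FALSE),
            class = c("gonad_summary", "data.frame"))
}
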