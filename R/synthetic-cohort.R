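#' Draw one battery item for one diagnostic group
#'
#' One seeded draw from the item's generative distribution: a normal with
#' the group's mean and SD, clipped (censored) to the item's legal range and
#' rounded according to the item class — plain integers for age, HADS and
#' NPQ scores, even integers for DHI subscales (items score 0/2/4),
#' untouched for continuous measurements. Uses the current RNG state.
#'
#' @param diagnosis One of `"PPPD"`, `"CDA"`, `"UVH"`, `"UD"`.
#' @param item Item name (a key of `params$items`).
#' @param n Number of draws.
#' @param params A `group_params` list.
#' @return Numeric vector of length `n`.
#' @export
sample_item <- function(diagnosis, item, n = 1,
                        params = default_group_params()) {
  it <- params$items[[item]]
  if (is.null(it))
    stop(sprintf("unknown item '%s'", item), call. = FALSE)
  cell <- it[[diagnosis]]
  if (is.null(cell))
    stop(sprintf("no parameters for group '%s'", diagnosis), call. = FALSE)
  round_item(stats::rnorm(n, cell$mean, cell$sd), it)
}

round_item <- function(v, it) {
  v <- pmin(pmax(v, it$range[1]), it$range[2])
  switch(it$class,
         integer = round(v),
         even = 2 * round(v / 2),
         continuous = v,
         stop(sprintf("unknown item class '%s'", it$class), call. = FALSE))
}

#' Construct a caloric quadruple with a prescribed canal paresis
#'
#' Builds four per-ear, per-temperature maximum slow-phase velocities whose
#' Jongkees canal paresis equals `target_cp` exactly: the stronger and
#' weaker ear sums are `total (1 + cp/100)/2` and `total (1 - cp/100)/2`,
#' each split between warm and cool by a random proportion. When
#' `target_dp` is given, the split is instead solved so the directional
#' preponderance also equals its target (always feasible for cp, dp in
#' \[0, 100\]); the beating direction is then chosen at random.
#'
#' @param target_cp Canal paresis percentage in \[0, 100\]. Vectorised.
#' @param target_total Summed response of all four irrigations
#'   (degrees/second, > 0).
#' @param weaker_side `"left"`, `"right"`, or `"none"` (requires
#'   `target_cp == 0`).
#' @param target_dp Optional directional preponderance percentage in
#'   \[0, 100\].
#' @return data.frame with columns `right_warm`, `right_cool`, `left_warm`,
#'   `left_cool`.
#' @export
generate_caloric_raw <- function(target_cp, target_total, weaker_side,
                                 target_dp = NULL) {
  if (any(target_cp < 0 | target_cp > 100))
    stop("target_cp must be in [0, 100]", call. = FALSE)
  if (any(target_total <= 0))
    stop("target_total must be positive", call. = FALSE)
  if (any(weaker_side == "none" & target_cp > 0))
    stop("weaker_side 'none' requires target_cp = 0", call. = FALSE)
  k <- max(length(target_cp), length(target_total), length(weaker_side))
  target_cp <- rep_len(target_cp, k)
  total <- rep_len(target_total, k)
  weaker_side <- rep_len(weaker_side, k)
  # a = (right sum) - (left sum); weaker side has the smaller sum
  a <- ifelse(weaker_side == "right", -1, 1) * total * target_cp / 100
  s_right <- (total + a) / 2
  s_left <- (total - a) / 2
  if (is.null(target_dp)) {
    x <- stats::runif(k) * s_right               # right_warm
    y <- stats::runif(k) * s_left                # left_warm
  } else {
    if (any(target_dp < 0 | target_dp > 100))
      stop("target_dp must be in [0, 100]", call. = FALSE)
    target_dp <- rep_len(target_dp, k)
    # b = (right-beating) - (left-beating) total; direction random
    b <- ifelse(stats::runif(k) < 0.5, 1, -1) * total * target_dp / 100
    lo <- pmax(0, (a + b) / 2)
    hi <- pmin(s_right, s_left + (a + b) / 2)
    x <- lo + stats::runif(k) * (hi - lo)
    y <- x - (a + b) / 2
  }
  # boundary draws can undershoot zero by a rounding epsilon
  data.frame(right_warm = pmax(0, x), right_cool = pmax(0, s_right - x),
             left_warm = pmax(0, y), left_cool = pmax(0, s_left - y))
}

#' Generate a labeled synthetic chronic-vestibular-syndrome cohort
#'
#' Simulates a cohort whose per-group distributions, sample sizes,
#' missingness pattern and vHIT categorical rates emulate the published
#' group-level summary statistics: four diagnostic groups (PPPD 92, CDA 44,
#' UVH 31, UD 37) plus an excluded "OTHER" stratum (27). Items are drawn
#' independently within patient from clipped normals (see [sample_item()]);
#' questionnaire totals are computed by summation, never drawn; caloric
#' CP%/DP% arise from a raw quadruple built by [generate_caloric_raw()]; a
#' vHIT sub-cohort (56 PPPD, 6 UVH) receives gains and Bernoulli
#' catch-up-saccade status; per-item missingness is injected exactly per
#' cell by [inject_missingness()].
#'
#' The generation is fully deterministic given `seed`: one global seed
#' spawns a named sub-seed per stage (values, vHIT, missingness), so stages
#' are independently reproducible.
#'
#' @param params A `group_params` list (defaults to the shipped study
#'   parameters).
#' @param seed Integer seed governing all randomness.
#' @param scale Positive factor multiplying every group size (rounded);
#'   `scale = 1` reproduces the study sizes (231 patients in total).
#' @return A data.frame of patient records with attributes `scale`, `seed`
#'   and `complete_case_n`; column `complete_case` marks records of the four
#'   diagnostic groups with all five algorithm inputs (age, HADS-A, NPQ
#'   visual, NPQ total, CP%) observed.
#' @export
generate_cohort <- function(params = default_group_params(), seed = 1,
                            scale = 1) {
  validate_group_params(params)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  set.seed(seed)
  stage_seed <- sample.int(2147483646L, 3)
  groups <- c("PPPD", "CDA", "UVH", "UD")
  sizes <- vapply(params$group_sizes, function(s) as.integer(round(s * scale)),
                  integer(1))

  set.seed(stage_seed[1])
  recs <- lapply(groups, function(g) simulate_group(g, sizes[[g]], params))
  other <- simulate_other(sizes[["OTHER"]], params)
  cohort <- rbind(do.call(rbind, recs), other)
  cohort$id <- sprintf("P%04d", seq_len(nrow(cohort)))
  cohort <- cohort[c("id", setdiff(names(cohort), "id"))]

  set.seed(stage_seed[2])
  cohort <- generate_vhit_subcohort(cohort, params, scale = scale)

  cohort <- inject_missingness(cohort, params, seed = stage_seed[3],
                               scale = scale)
  validate_scores(cohort)
  attr(cohort, "seed") <- seed
  attr(cohort, "scale") <- scale
  rownames(cohort) <- NULL
  cohort
}

simulate_group <- function(g, n, params) {
  draw <- function(item) sample_item(g, item, n, params)
  rec <- data.frame(
    diagnosis = rep(g, n),
    sex = ifelse(stats::runif(n) < params$female_rate, "F", "M"),
    age = draw("age"),
    hads_anxiety = draw("hads_anxiety"),
    hads_depression = draw("hads_depression"),
    dhi_physical = draw("dhi_physical"),
    dhi_emotional = draw("dhi_emotional"),
    dhi_functional = draw("dhi_functional"),
    npq_upright = draw("npq_upright"),
    npq_movement = draw("npq_movement"),
    npq_visual = draw("npq_visual"),
    cvemp_iaar = draw("cvemp_iaar"),
    ovemp_iaar = draw("ovemp_iaar"),
    foam_ratio = draw("foam_ratio"),
    romberg_ratio_foam = draw("romberg_ratio_foam"),
    vor_dp_percent = draw("vor_dp_percent"),
    stringsAsFactors = FALSE
  )
  rec$hads_total <- rec$hads_anxiety + rec$hads_depression
  rec$dhi_total <- rec$dhi_physical + rec$dhi_emotional + rec$dhi_functional
  rec$npq_total <- rec$npq_upright + rec$npq_movement + rec$npq_visual
  # caloric: CP% and DP% targets drawn per cell, realised through one raw
  # quadruple so the stored asymmetries are exactly consistent with it
  tot_spv <- params$caloric_total_spv
  total <- pmin(pmax(stats::rnorm(n, tot_spv$mean, tot_spv$sd),
                     tot_spv$min), tot_spv$max)
  cp_target <- draw("cp_percent")
  dp_target <- draw("dp_percent")
  side <- ifelse(cp_target == 0, "none",
                 ifelse(stats::runif(n) < 0.5, "left", "right"))
  raw <- generate_caloric_raw(cp_target, total, side, dp_target)
  cp <- jongkees_cp(raw$right_warm, raw$right_cool,
                    raw$left_warm, raw$left_cool)
  rec$caloric_right_warm <- raw$right_warm
  rec$caloric_right_cool <- raw$right_cool
  rec$caloric_left_warm <- raw$left_warm
  rec$caloric_left_cool <- raw$left_cool
  rec$cp_percent <- cp$cp_percent
  rec$cp_weaker_side <- cp$weaker_side
  rec$dp_percent <- directional_preponderance(
    raw$right_warm, raw$right_cool, raw$left_warm, raw$left_cool)
  rec$vhit_gain_better <- NA_real_
  rec$vhit_gain_worse <- NA_real_
  rec$vhit_ar <- NA_real_
  rec$cus_present <- NA
  rec
}

simulate_other <- function(n, params) {
  # excluded stratum: carries demographics only, mirroring the study's
  # restriction of every analysis to the four major diagnoses
  age_par <- params$other_stratum_age
  rec <- data.frame(
    diagnosis = rep("OTHER", n),
    sex = ifelse(stats::runif(n) < params$female_rate, "F", "M"),
    age = round(pmin(pmax(stats::rnorm(n, age_par$mean, age_par$sd), 0), 100)),
    stringsAsFactors = FALSE
  )
  template <- c("hads_anxiety", "hads_depression", "dhi_physical",
                "dhi_emotional", "dhi_functional", "npq_upright",
                "npq_movement", "npq_visual", "cvemp_iaar", "ovemp_iaar",
                "foam_ratio", "romberg_ratio_foam", "vor_dp_percent",
                "hads_total", "dhi_total", "npq_total",
                "caloric_right_warm", "caloric_right_cool",
                "caloric_left_warm", "caloric_left_cool",
                "cp_percent", "dp_percent",
                "vhit_gain_better", "vhit_gain_worse", "vhit_ar")
  for (col in template) rec[[col]] <- NA_real_
  rec$cp_weaker_side <- NA_character_
  rec$cus_present <- NA
  rec
}

#' Assign vHIT measurements to a PPPD/UVH sub-cohort
#'
#' Picks a random sub-cohort (56 PPPD and 6 UVH at `scale = 1`) and assigns
#' lateral-canal VOR gains (clipped normals per the published sub-cohort
#' means/SDs, with better >= worse enforced by ordering the pair), the
#' asymmetry ratio derived through [vhit_asymmetry()], and catch-up-saccade
#' status drawn Bernoulli with rates 1/56 (PPPD) and 3/6 (UVH). Uses the
#' current RNG state.
#'
#' @param cohort Cohort data.frame containing PPPD and UVH records.
#' @param params A `group_params` list.
#' @param scale Size multiplier matching the cohort.
#' @return `cohort` with vHIT columns filled for the selected records.
#' @export
generate_vhit_subcohort <- function(cohort, params, scale = 1) {
  vh <- params$vhit
  rng <- vh$gain_range
  for (g in names(vh$subcohort_sizes)) {
    m <- as.integer(round(vh$subcohort_sizes[[g]] * scale))
    idx_g <- which(cohort$diagnosis == g)
    if (m > length(idx_g))
      stop(sprintf("vHIT sub-cohort for %s larger than the group", g),
           call. = FALSE)
    idx <- if (m > 0) sample(idx_g, m) else integer(0)
    g1 <- pmin(pmax(stats::rnorm(m, vh$gain_better[[g]]$mean,
                                 vh$gain_better[[g]]$sd), rng[1]), rng[2])
    g2 <- pmin(pmax(stats::rnorm(m, vh$gain_worse[[g]]$mean,
                                 vh$gain_worse[[g]]$sd), rng[1]), rng[2])
    better <- pmax(g1, g2)
    worse <- pmin(g1, g2)
    # guard the degenerate both-zero pair (clipping can produce it)
    zero <- better + worse == 0
    better[zero] <- 0.01
    cohort$vhit_gain_better[idx] <- better
    cohort$vhit_gain_worse[idx] <- worse
    cohort$vhit_ar[idx] <- vhit_asymmetry(better, worse)$ar
    rate <- vh$cus_positive_counts[[g]] / vh$subcohort_sizes[[g]]
    cohort$cus_present[idx] <- stats::runif(m) < rate
  }
  cohort
}

# Instrument blocks sharing one missingness mask: the published per-item
# n's are identical within each block, and a shared mask preserves
# subscale/total additivity.
missingness_blocks <- function() {
  list(
    hads = c("hads_anxiety", "hads_depression", "hads_total"),
    dhi = c("dhi_physical", "dhi_emotional", "dhi_functional", "dhi_total"),
    npq = c("npq_upright", "npq_movement", "npq_visual", "npq_total"),
    caloric = c("caloric_right_warm", "caloric_right_cool",
                "caloric_left_warm", "caloric_left_cool",
                "cp_percent", "cp_weaker_side", "dp_percent"),
    cvemp = "cvemp_iaar",
    ovemp = "ovemp_iaar",
    posturography = c("foam_ratio", "romberg_ratio_foam"),
    rotatory_chair = "vor_dp_percent"
  )
}

# representative item per block, for looking up the per-cell available n
block_lead_item <- c(hads = "hads_anxiety", dhi = "dhi_physical",
                     npq = "npq_upright", caloric = "cp_percent",
                     cvemp = "cvemp_iaar", ovemp = "ovemp_iaar",
                     posturography = "foam_ratio",
                     rotatory_chair = "vor_dp_percent")

#' Inject the published per-cell missingness pattern
#'
#' For every diagnostic group x instrument block, exactly
#' `group size - round(n_available * scale)` records have that block set to
#' missing, chosen by seeded weighted sampling without replacement. Each
#' patient carries a latent missingness propensity (`exp(kappa * z)`,
#' `z ~ N(0,1)`), so blocks tend to go missing in the same patients — as in
#' retrospective chart data, where incomplete workups cluster — making the
#' complete-case count an emergent property rather than a forced one.
#' `kappa = 0` gives independent per-block masks.
#'
#' @param cohort Cohort data.frame (four-group records; the OTHER stratum is
#'   untouched).
#' @param params A `group_params` list.
#' @param seed Integer seed for the mask draw.
#' @param scale Size multiplier matching the cohort.
#' @param kappa Missingness-propensity concentration (>= 0); default 2.
#' @return `cohort` with `NA`s injected, a logical `complete_case` column,
#'   and attribute `complete_case_n`.
#' @export
inject_missingness <- function(cohort, params, seed, scale = 1, kappa = 2) {
  set.seed(seed)
  blocks <- missingness_blocks()
  for (g in c("PPPD", "CDA", "UVH", "UD")) {
    idx_g <- which(cohort$diagnosis == g)
    size_g <- length(idx_g)
    propensity <- exp(kappa * stats::rnorm(size_g))
    for (b in names(blocks)) {
      n_avail <- as.integer(round(params$items[[block_lead_item[[b]]]][[g]]$n *
                                    scale))
      m <- size_g - min(n_avail, size_g)
      if (m <= 0) next
      drop <- idx_g[sample.int(size_g, m, prob = propensity)]
      for (col in blocks[[b]]) cohort[[col]][drop] <- NA
    }
  }
  cohort$complete_case <- cohort$diagnosis %in% c("PPPD", "CDA", "UVH", "UD") &
    !is.na(cohort$age) & !is.na(cohort$hads_anxiety) &
    !is.na(cohort$npq_visual) & !is.na(cohort$npq_total) &
    !is.na(cohort$cp_percent)
  attr(cohort, "complete_case_n") <- sum(cohort$complete_case)
  cohort
}
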