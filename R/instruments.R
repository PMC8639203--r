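#' Canal paresis percentage (Jongkees formula)
#'
#' Computes the relative asymmetry of the bithermal caloric responses between
#' the two ears from the four maximum slow-phase velocities, as
#' \deqn{CP\% = \left|\frac{(R_w + R_c) - (L_w + L_c)}{R_w + R_c + L_w + L_c}\right| \times 100.}
#' A CP% above 20 is the conventional criterion for significant unilateral
#' caloric weakness.
#'
#' @param right_warm,right_cool,left_warm,left_cool Maximum slow-phase
#'   velocity of the caloric nystagmus (degrees/second, non-negative) for
#'   each ear x temperature combination. Vectorised.
#' @return A data.frame with columns `cp_percent` (in \[0, 100\]) and
#'   `weaker_side` (`"left"`, `"right"`, or `"none"` on an exact tie).
#' @examples
#' jongkees_cp(30, 20, 15, 10) # 33.33, weaker side left
#' @export
jongkees_cp <- function(right_warm, right_cool, left_warm, left_cool) {
  check_caloric(right_warm, right_cool, left_warm, left_cool)
  right <- right_warm + right_cool
  left <- left_warm + left_cool
  total <- right + left
  cp <- abs(right - left) / total * 100
  side <- ifelse(right < left, "right", ifelse(left < right, "left", "none"))
  data.frame(cp_percent = cp, weaker_side = side, stringsAsFactors = FALSE)
}

#' Directional preponderance of the caloric nystagmus
#'
#' Asymmetry between the right-beating (right-warm + left-cool) and
#' left-beating (left-warm + right-cool) caloric response totals, expressed
#' as a percentage of the grand total.
#'
#' @inheritParams jongkees_cp
#' @return Numeric vector of DP% values in \[0, 100\].
#' @export
directional_preponderance <- function(right_warm, right_cool, left_warm,
                                      left_cool) {
  check_caloric(right_warm, right_cool, left_warm, left_cool)
  right_beating <- right_warm + left_cool
  left_beating <- left_warm + right_cool
  abs(right_beating - left_beating) /
    (right_beating + left_beating) * 100
}

check_caloric <- function(rw, rc, lw, lc) {
  vals <- cbind(rw, rc, lw, lc)
  if (any(vals < 0, na.rm = TRUE))
    stop("caloric responses must be non-negative", call. = FALSE)
  if (any(rowSums(vals) == 0, na.rm = TRUE))
    stop("all four caloric responses are zero: asymmetry undefined",
         call. = FALSE)
  invisible(NULL)
}

#' VEMP interaural asymmetry ratio
#'
#' Signed asymmetry of the normalized VEMP peak-to-peak amplitudes
#' (p13-n23 for cVEMP, n10-p15 for oVEMP):
#' \deqn{IAAR = (A_r - A_l) / (A_r + A_l) \times 100.}
#' Positive values mean the right side is larger; |IAAR| > 33.3 is the
#' conventional criterion for unilateral otolith dysfunction.
#'
#' @param amp_right,amp_left Normalized amplitudes, non-negative, with
#'   `amp_right + amp_left > 0`. Vectorised.
#' @return Signed percentage in \[-100, 100\].
#' @export
vemp_iaar <- function(amp_right, amp_left) {
  if (any(amp_right < 0 | amp_left < 0, na.rm = TRUE))
    stop("VEMP amplitudes must be non-negative", call. = FALSE)
  if (any(amp_right + amp_left == 0, na.rm = TRUE))
    stop("both VEMP amplitudes are zero: asymmetry undefined", call. = FALSE)
  (amp_right - amp_left) / (amp_right + amp_left) * 100
}

#' vHIT gain asymmetry ratio
#'
#' Absolute asymmetry of the lateral-canal VOR gains measured at 60 ms:
#' \deqn{AR = |(RL - LL) / (RL + LL)| \times 100.}
#'
#' @param gain_right,gain_left VOR gains for the right and left lateral
#'   canals, non-negative, with a positive sum. Vectorised.
#' @return A data.frame with `ar` (percentage in \[0, 100\]),
#'   `gain_better` = max of the two gains and `gain_worse` = min.
#' @export
vhit_asymmetry <- function(gain_right, gain_left) {
  if (any(gain_right < 0 | gain_left < 0, na.rm = TRUE))
    stop("VOR gains must be non-negative", call. = FALSE)
  if (any(gain_right + gain_left == 0, na.rm = TRUE))
    stop("both VOR gains are zero: asymmetry undefined", call. = FALSE)
  data.frame(
    ar = abs(gain_right - gain_left) / (gain_right + gain_left) * 100,
    gain_better = pmax(gain_right, gain_left),
    gain_worse = pmin(gain_right, gain_left)
  )
}

#' Default abnormality thresholds for the vestibular test battery
#'
#' Strict (">" / "<") cutoffs: CP% > 20 for unilateral caloric weakness,
#' |IAAR| > 33.3 for unilateral cVEMP/oVEMP dysfunction, |VOR-DP| > 12 on
#' the rotatory chair test, and vHIT gain (worse side) < 0.6 for low gain.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(cp = 20, iaar = 33.3, vor_dp = 12, vhit_gain = 0.6)
}

#' Flag instrument-level abnormalities for a cohort
#'
#' Applies the conventional strict cutoffs to the derived instrument
#' quantities. Missing inputs propagate to missing flags (`NA`), they never
#' error.
#'
#' @param cohort Cohort data.frame (see [generate_cohort()] for the schema).
#' @param thresholds Named list as returned by [default_thresholds()].
#' @return `cohort` with logical columns `cp_abnormal`, `cvemp_abnormal`,
#'   `ovemp_abnormal`, `vordp_abnormal`, `vhit_low_gain` appended.
#' @export
flag_abnormalities <- function(cohort, thresholds = default_thresholds()) {
  cohort$cp_abnormal <- cohort$cp_percent > thresholds$cp
  cohort$cvemp_abnormal <- abs(cohort$cvemp_iaar) > thresholds$iaar
  cohort$ovemp_abnormal <- abs(cohort$ovemp_iaar) > thresholds$iaar
  cohort$vordp_abnormal <- abs(cohort$vor_dp_percent) > thresholds$vor_dp
  cohort$vhit_low_gain <- cohort$vhit_gain_worse < thresholds$vhit_gain
  cohort
}

# Questionnaire structure: item class, subscale ranges, and additivity.
questionnaire_spec <- function() {
  list(
    hads = list(parts = c(hads_anxiety = 21, hads_depression = 21),
                total = "hads_total", step = 1L),
    dhi = list(parts = c(dhi_physical = 28, dhi_emotional = 36,
                         dhi_functional = 36),
               total = "dhi_total", step = 2L),
    npq = list(parts = c(npq_upright = 24, npq_movement = 24,
                         npq_visual = 24),
               total = "npq_total", step = 1L)
  )
}

#' Validate questionnaire score structure
#'
#' Checks, for every record with a fully observed questionnaire block, that
#' (i) each subscale is an integer (even integer for the DHI, whose items
#' score 0/2/4) within its range — HADS subscales 0–21, DHI physical 0–28 /
#' emotional 0–36 / functional 0–36, NPQ factors 0–24 — and (ii) the stored
#' total equals the subscale sum (HADS total = anxiety + depression, DHI
#' total 0–100, NPQ total 0–72). Blocks with any missing component are
#' skipped: missingness is legitimate, inconsistency is not.
#'
#' @param cohort Cohort data.frame.
#' @return `cohort`, invisibly, if valid; otherwise an error naming the
#'   offending field and record id.
#' @export
validate_scores <- function(cohort) {
  qs <- questionnaire_spec()
  id <- if (!is.null(cohort$id)) cohort$id else seq_len(nrow(cohort))
  for (block in qs) {
    parts <- names(block$parts)
    present_cols <- intersect(c(parts, block$total), names(cohort))
    if (length(present_cols) == 0) next
    for (p in intersect(parts, names(cohort))) {
      v <- cohort[[p]]
      ok <- is.na(v) | (v >= 0 & v <= block$parts[[p]] & v %% block$step == 0)
      if (!all(ok))
        stop(sprintf("%s out of range or wrong granularity for record %s",
                     p, paste(id[!ok], collapse = ", ")), call. = FALSE)
    }
    if (block$total %in% names(cohort) && all(parts %in% names(cohort))) {
      sums <- Reduce(`+`, cohort[parts])
      tot <- cohort[[block$total]]
      complete <- !is.na(sums)
      bad <- complete & !is.na(tot) & tot != sums
      if (any(bad))
        stop(sprintf("%s does not equal its subscale sum for record %s",
                     block$total, paste(id[bad], collapse = ", ")),
             call. = FALSE)
      bad_na <- complete & is.na(tot)
      if (any(bad_na))
        stop(sprintf("%s missing although all subscales present for record %s",
                     block$total, paste(id[bad_na], collapse = ", ")),
             call. = FALSE)
    }
  }
  invisible(cohort)
}
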