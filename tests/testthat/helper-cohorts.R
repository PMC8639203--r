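# Shared fixtures: cohorts are expensive enough to cache across tests.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed = 1, scale = 1) {
  key <- sprintf("s%d_x%g", seed, scale)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(seed = seed, scale = scale)
  .cohort_cache[[key]]
}

# A minimal hand-built cohort for algorithm tests: every column the
# classifier touches, nothing stochastic.
tiny_cohort <- function() {
  data.frame(
    id = sprintf("T%02d", 1:6),
    diagnosis = c("PPPD", "UVH", "CDA", "UD", "PPPD", "UVH"),
    age = c(45, 70, 30, 65, 50, 68),
    hads_anxiety = c(5, 4, 12, 3, 5, 2),
    npq_visual = c(13, 2, 4, 3, 13, 1),
    npq_total = c(38, 10, 15, 12, 38, 8),
    cp_percent = c(10, 60, 5, 8, 10, 55),
    cus_present = c(FALSE, TRUE, FALSE, FALSE, FALSE, NA),
    stringsAsFactors = FALSE
  )
}

# Printed study thresholds, used to pin the block structure.
printed_thresholds <- c(cp_percent = 19.8, npq_visual = 10.5,
                        npq_total = 33.5, hads_anxiety = 8.5, age = 48.5)

battery_from_thresholds <- function(thr = printed_thresholds) {
  lapply(as.list(thr), function(v) list(youden = list(threshold = v)))
}

# Random labeled mini-cohorts for the structural classifier properties.
random_mini_cohort <- function(n = 40) {
  data.frame(
    diagnosis = sample(c("PPPD", "CDA", "UVH", "UD"), n, replace = TRUE),
    age = round(runif(n, 15, 85)),
    hads_anxiety = sample(0:21, n, replace = TRUE),
    npq_visual = sample(0:24, n, replace = TRUE),
    npq_total = sample(0:72, n, replace = TRUE),
    cp_percent = runif(n, 0, 100),
    cus_present = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
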