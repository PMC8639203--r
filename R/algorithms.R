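#' Build a single threshold-rule block
#'
#' A block is one disease plus a list of criteria; each criterion compares
#' a cohort column against a threshold (`"ge"`: value >= threshold, `"lt"`:
#' value < threshold) or requires a logical column to be `TRUE`
#' (`"true"`). A block fires when `any` (default) or `all` of its criteria
#' hold.
#'
#' @param disease Disease the block diagnoses (`"PPPD"`, `"UVH"`, `"CDA"`).
#' @param criteria List of `list(item =, op =, threshold =)` entries.
#' @param combinator `"any"` or `"all"`.
#' @return Object of class `"rule_block"`.
#' @export
rule_block <- function(disease, criteria, combinator = c("any", "all")) {
  combinator <- match.arg(combinator)
  if (length(criteria) == 0)
    stop("a rule block needs at least one criterion", call. = FALSE)
  for (cr in criteria) {
    if (!cr$op %in% c("ge", "lt", "true"))
      stop(sprintf("unknown criterion operator '%s'", cr$op), call. = FALSE)
    if (cr$op != "true" && !is.finite(cr$threshold))
      stop("criterion thresholds must be finite", call. = FALSE)
  }
  structure(list(disease = disease, criteria = criteria,
                 combinator = combinator), class = "rule_block")
}

#' Build the three disease rule blocks from a derived battery
#'
#' Maps Youden-optimal thresholds onto the published block structure:
#' PPPD fires on NPQ total or visual stimulation score at/above threshold;
#' UVH on CP% at/above threshold or presence of catch-up saccades; CDA on
#' HADS-A at/above threshold or age below threshold. The within-block
#' combinator defaults to OR (`"any"`).
#'
#' @param battery Named list of `roc_analysis` objects from
#'   [derive_battery()] (keys `cp_percent`, `npq_visual`, `npq_total`,
#'   `hads_anxiety`, `age`).
#' @param cus_rule Include the catch-up-saccade criterion in the UVH block?
#' @param combinator `"any"` (default) or `"all"` for every block.
#' @return Named list of three `rule_block`s (`PPPD`, `UVH`, `CDA`).
#' @export
build_blocks <- function(battery, cus_rule = TRUE,
                         combinator = c("any", "all")) {
  combinator <- match.arg(combinator)
  needed <- c("cp_percent", "npq_visual", "npq_total", "hads_anxiety", "age")
  missing_items <- setdiff(needed, names(battery))
  if (length(missing_items))
    stop("battery is missing: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  thr <- function(item) battery[[item]]$youden$threshold
  uvh_criteria <- list(list(item = "cp_percent", op = "ge",
                            threshold = thr("cp_percent")))
  if (cus_rule)
    uvh_criteria <- c(uvh_criteria,
                      list(list(item = "cus_present", op = "true",
                                threshold = NA)))
  list(
    PPPD = rule_block("PPPD", list(
      list(item = "npq_total", op = "ge", threshold = thr("npq_total")),
      list(item = "npq_visual", op = "ge", threshold = thr("npq_visual"))
    ), combinator),
    UVH = rule_block("UVH", uvh_criteria, combinator),
    CDA = rule_block("CDA", list(
      list(item = "hads_anxiety", op = "ge", threshold = thr("hads_anxiety")),
      list(item = "age", op = "lt", threshold = thr("age"))
    ), combinator)
  )
}

# the canonical order of the six algorithms: 1-2 diagnose PPPD first,
# 3-4 UVH first, 5-6 CDA first
algorithm_orders <- function() {
  list(`1` = c("PPPD", "UVH", "CDA"), `2` = c("PPPD", "CDA", "UVH"),
       `3` = c("UVH", "PPPD", "CDA"), `4` = c("UVH", "CDA", "PPPD"),
       `5` = c("CDA", "PPPD", "UVH"), `6` = c("CDA", "UVH", "PPPD"))
}

#' Enumerate the six ordered diagnostic algorithms
#'
#' All 3! orderings of the three disease blocks, with undifferentiated
#' dizziness (UD) as the fixed fallback when no block fires. Algorithms 1-2
#' test PPPD first, 3-4 UVH first, 5-6 CDA first.
#'
#' @param blocks Named list of three `rule_block`s from [build_blocks()].
#' @return Named list of six objects of class `"diagnostic_algorithm"`,
#'   each with `name`, `blocks` (ordered), `fallback = "UD"`.
#' @export
enumerate_algorithms <- function(blocks) {
  diseases <- vapply(blocks, `[[`, character(1), "disease")
  if (!setequal(diseases, c("PPPD", "UVH", "CDA")) ||
      anyDuplicated(diseases))
    stop("need exactly one block each for PPPD, UVH and CDA", call. = FALSE)
  names(blocks) <- diseases
  orders <- algorithm_orders()
  Map(function(nm, ord) {
    structure(list(name = paste("Algorithm", nm),
                   blocks = blocks[ord], fallback = "UD"),
              class = "diagnostic_algorithm")
  }, names(orders), orders)
}

criterion_met <- function(cohort, cr) {
  v <- cohort[[cr$item]]
  if (is.null(v))
    stop(sprintf("cohort lacks column '%s'", cr$item), call. = FALSE)
  met <- switch(cr$op,
                ge = v >= cr$threshold,
                lt = v < cr$threshold,
                true = v %in% TRUE)
  met[is.na(met)] <- FALSE   # a missing measurement never fires a criterion
  met
}

block_fires <- function(cohort, block) {
  hits <- vapply(block$criteria, function(cr) criterion_met(cohort, cr),
                 logical(nrow(cohort)))
  hits <- matrix(hits, nrow = nrow(cohort))
  if (block$combinator == "any") rowSums(hits) > 0
  else rowSums(hits) == length(block$criteria)
}

#' Classify cohort records with one sequential algorithm
#'
#' Evaluates the algorithm's blocks in order; the first block that fires
#' determines the diagnosis, and records firing no block fall back to UD.
#' Under the `"complete_required"` policy (the study evaluated only
#' patients who received all test batteries), records missing any of the
#' five core inputs (age, HADS-A, NPQ visual, NPQ total, CP%) receive `NA`;
#' under `"missing_negative"` every record is classified and missing
#' measurements simply never satisfy a criterion. Catch-up-saccade status,
#' measured only in a vHIT sub-cohort, is treated as criterion-not-met when
#' absent under both policies.
#'
#' @param cohort Cohort data.frame.
#' @param algorithm A `diagnostic_algorithm`.
#' @param missing_policy `"complete_required"` (default) or
#'   `"missing_negative"`.
#' @return Character vector of predicted diagnoses (`NA` for excluded
#'   records).
#' @export
classify <- function(cohort, algorithm,
                     missing_policy = c("complete_required",
                                        "missing_negative")) {
  missing_policy <- match.arg(missing_policy)
  pred <- rep(algorithm$fallback, nrow(cohort))
  undecided <- rep(TRUE, nrow(cohort))
  for (block in algorithm$blocks) {
    fire <- block_fires(cohort, block)
    pred[undecided & fire] <- block$disease
    undecided <- undecided & !fire
  }
  if (missing_policy == "complete_required") {
    core <- c("age", "hads_anxiety", "npq_visual", "npq_total", "cp_percent")
    incomplete <- Reduce(`|`, lapply(cohort[core], is.na))
    pred[incomplete] <- NA_character_
  }
  pred
}

#' Evaluate a diagnostic algorithm on a labeled cohort
#'
#' Restricts to records whose true diagnosis is one of the four groups
#' (and, under `"complete_required"`, to complete cases), classifies them,
#' and reports the confusion matrix, per-class recall, and the overall
#' accuracy excluding UD — the proportion of correct classifications among
#' patients whose true diagnosis is PPPD, UVH or CDA (UD-true patients
#' never enter this denominator).
#'
#' @inheritParams classify
#' @return Object of class `"evaluation_report"`: list with `algorithm`,
#'   `confusion` (true x predicted), `per_class_recall` (percent, named),
#'   `overall_accuracy_excl_ud` (percent, 1 decimal), `n_evaluated`,
#'   `n_excluded_incomplete`.
#' @export
evaluate <- function(cohort, algorithm,
                     missing_policy = c("complete_required",
                                        "missing_negative")) {
  missing_policy <- match.arg(missing_policy)
  four <- cohort[cohort$diagnosis %in% c("PPPD", "CDA", "UVH", "UD"), ]
  pred <- classify(four, algorithm, missing_policy)
  keep <- !is.na(pred)
  n_excluded <- sum(!keep)
  four <- four[keep, ]
  pred <- pred[keep]
  if (nrow(four) == 0)
    stop("no evaluable records", call. = FALSE)
  lv <- c("PPPD", "CDA", "UVH", "UD")
  confusion <- table(true = factor(four$diagnosis, lv),
                     predicted = factor(pred, lv))
  recall <- 100 * diag(confusion) / pmax(1, rowSums(confusion))
  correct <- diag(confusion)
  n_class <- rowSums(confusion)
  structure(list(
    algorithm = algorithm$name,
    confusion = confusion,
    per_class_recall = round(recall, 1),
    overall_accuracy_excl_ud = aggregate_overall(correct, n_class,
                                                 exclude = "UD"),
    n_evaluated = nrow(four),
    n_excluded_incomplete = n_excluded
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s: overall accuracy (excl. UD) %.1f%% on %d patients (%d excluded as incomplete)\n",
              x$algorithm, x$overall_accuracy_excl_ud, x$n_evaluated,
              x$n_excluded_incomplete))
  cat("Per-class recall (%):\n")
  print(x$per_class_recall)
  cat("Confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Aggregate per-class correct counts into an overall accuracy
#'
#' \eqn{100 \sum_c correct_c / \sum_c n_c} over the non-excluded classes,
#' reported to one decimal. With the default exclusion this is the overall
#' diagnostic accuracy for all diseases except UD.
#'
#' @param correct Named vector of correctly classified counts per class.
#' @param n Named vector of true-class sizes (same names).
#' @param exclude Classes to drop from both sums (default `"UD"`).
#' @return Percentage rounded to one decimal.
#' @export
aggregate_overall <- function(correct, n, exclude = "UD") {
  if (any(correct < 0) || any(n < 0) || any(correct > n))
    stop("need 0 <= correct <= n per class", call. = FALSE)
  keep <- !(names(n) %in% exclude)
  if (sum(n[keep]) == 0)
    stop("no patients in the included classes", call. = FALSE)
  round(100 * sum(correct[keep]) / sum(n[keep]), 1)
}
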