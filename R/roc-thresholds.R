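#' ROC operating points over all candidate thresholds
#'
#' Candidate thresholds are the midpoints between adjacent distinct observed
#' scores plus the two infinite endpoints. Under the `"greater"` orientation
#' a patient is called positive when score >= threshold (sensitivity =
#' fraction of target patients at or above it); under `"less"`, when
#' score < threshold. With midpoints, equality with a threshold cannot occur
#' on integer scores, which is why questionnaire and age cutoffs come out as
#' half-integers.
#'
#' @param scores Numeric scores, no missing values.
#' @param labels Logical vector, `TRUE` for the target disease.
#' @param orientation `"greater"` if larger scores indicate the target
#'   disease, `"less"` otherwise.
#' @return data.frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_points <- function(scores, labels,
                       orientation = c("greater", "less")) {
  orientation <- match.arg(orientation)
  check_two_classes(scores, labels)
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (orientation == "greater") {
    sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  } else {
    sens <- vapply(thr, function(t) mean(pos < t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  }
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

check_two_classes <- function(scores, labels) {
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete", call. = FALSE)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a random target
#' patient scores on the disease side of a random non-target patient, ties
#' counted half.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, orientation = c("greater", "less")) {
  orientation <- match.arg(orientation)
  check_two_classes(scores, labels)
  n1 <- sum(labels)
  n2 <- sum(!labels)
  r <- rank(scores)
  a <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (orientation == "greater") a else 1 - a
}

#' Confidence interval for the AUC
#'
#' 95% (by default) two-sided interval via DeLong's method or the
#' stratified bootstrap, delegated to [pROC::ci.auc()], truncated to
#' \[0, 1\].
#'
#' @inheritParams roc_points
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param conf Confidence level.
#' @param boot_n Bootstrap resamples when `method = "bootstrap"`.
#' @return Numeric vector `c(lo, hi)`.
#' @export
auc_ci <- function(scores, labels, orientation = c("greater", "less"),
                   method = c("delong", "bootstrap"), conf = 0.95,
                   boot_n = 2000) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  check_two_classes(scores, labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("each class needs at least 2 members for a CI", call. = FALSE)
  direction <- if (orientation == "greater") "<" else ">"
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = direction,
                   quiet = TRUE)
  ci <- withCallingHandlers(
    pROC::ci.auc(roc, conf.level = conf, method = method, boot.n = boot_n),
    warning = function(w) {
      # pROC warns that a degenerate CI at AUC = 1 "can be misleading";
      # the truncated point interval is exactly what we report
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  c(max(0, ci[1]), min(1, ci[3]))
}

#' Youden-optimal operating point
#'
#' Selects the threshold maximizing the Youden index
#' J = sensitivity + specificity - 1; ties are broken by higher
#' sensitivity, then by lower threshold.
#'
#' @param points data.frame from [roc_points()].
#' @return List with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_threshold <- function(points) {
  if (nrow(points) == 0) stop("no ROC points", call. = FALSE)
  j <- points$sensitivity + points$specificity - 1
  ord <- order(-j, -points$sensitivity, points$threshold)
  best <- points[ord[1], ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, J = j[ord[1]])
}

#' Full ROC analysis for one item against one target disease
#'
#' Bundles [roc_points()], [roc_auc()], [auc_ci()] and
#' [youden_threshold()] into one object.
#'
#' @inheritParams auc_ci
#' @param item,target_disease Labels stored on the result.
#' @return Object of class `"roc_analysis"`: a list with `item`,
#'   `target_disease`, `orientation`, `n_target`, `n_rest`, `points`,
#'   `auc`, `auc_ci_95`, `youden` (threshold/sensitivity/specificity/J).
#' @export
roc_analysis <- function(scores, labels,
                         orientation = c("greater", "less"),
                         item = NULL, target_disease = NULL,
                         method = c("delong", "bootstrap")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  pts <- roc_points(scores, labels, orientation)
  out <- list(
    item = item, target_disease = target_disease,
    orientation = orientation,
    n_target = sum(labels), n_rest = sum(!labels),
    points = pts,
    auc = roc_auc(scores, labels, orientation),
    auc_ci_95 = auc_ci(scores, labels, orientation, method = method),
    youden = youden_threshold(pts)
  )
  class(out) <- "roc_analysis"
  out
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf(
    "ROC: %s -> %s (%s)\n  AUC %.3f (95%% CI %.3f-%.3f), n = %d vs %d\n",
    x$item, x$target_disease,
    ifelse(x$orientation == "greater", "higher indicates target",
           "lower indicates target"),
    x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$n_target, x$n_rest))
  cat(sprintf(
    "  Youden threshold %.4g: sensitivity %.1f%%, specificity %.1f%% (J = %.3f)\n",
    x$youden$threshold, 100 * x$youden$sensitivity,
    100 * x$youden$specificity, x$youden$J))
  invisible(x)
}

# battery definition: item -> target disease and orientation. Age runs the
# other way because CDA patients are the youngest group.
battery_definition <- function() {
  data.frame(
    item = c("cp_percent", "npq_visual", "npq_total", "hads_anxiety", "age"),
    target = c("UVH", "PPPD", "PPPD", "CDA", "CDA"),
    orientation = c("greater", "greater", "greater", "greater", "less"),
    stringsAsFactors = FALSE
  )
}

#' Derive the diagnostic test battery thresholds
#'
#' Runs a one-vs-rest ROC analysis within the four diagnostic groups for
#' each battery item: CP% for UVH, NPQ visual and total scores for PPPD,
#' and HADS-A score (higher) and age (lower) for CDA. By default each item
#' uses its available (non-missing) cases; `complete_case = TRUE` restricts
#' every analysis to records with all five algorithm inputs observed.
#'
#' @param cohort Cohort data.frame.
#' @param complete_case Use only complete-case records?
#' @param method CI method passed to [auc_ci()].
#' @return Named list of `roc_analysis` objects keyed by item.
#' @export
derive_battery <- function(cohort, complete_case = FALSE,
                           method = c("delong", "bootstrap")) {
  method <- match.arg(method)
  four <- cohort[cohort$diagnosis %in% c("PPPD", "CDA", "UVH", "UD"), ]
  if (complete_case) four <- four[four$complete_case, ]
  def <- battery_definition()
  out <- list()
  for (k in seq_len(nrow(def))) {
    item <- def$item[k]
    keep <- !is.na(four[[item]])
    scores <- four[[item]][keep]
    labels <- four$diagnosis[keep] == def$target[k]
    if (!any(labels) || all(labels))
      stop(sprintf("battery item %s: a class is empty", item), call. = FALSE)
    out[[item]] <- roc_analysis(scores, labels,
                                orientation = def$orientation[k],
                                item = item, target_disease = def$target[k],
                                method = method)
  }
  out
}
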