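#' Kruskal-Wallis test across groups
#'
#' Rank-based one-way comparison of k groups on midranks with tie
#' correction; the statistic is referred to a chi-square distribution with
#' k - 1 degrees of freedom. Thin wrapper over [stats::kruskal.test()]
#' returning the pieces the screening pipeline consumes.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List with `H` (statistic), `df`, and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("kruskal_wallis needs >= 2 non-empty groups", call. = FALSE)
  if (sum(lengths(groups)) < 3)
    stop("kruskal_wallis needs a total n of at least 3", call. = FALSE)
  if (length(unique(unlist(groups))) == 1)   # all tied: no evidence, H = 0
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn post-hoc pairwise comparisons
#'
#' All pairwise z tests on the pooled midranks after a Kruskal-Wallis
#' screen, with the usual tie correction
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}}
#' and two-sided p-values Bonferroni-multiplied by the number of pairs
#' (capped at 1).
#'
#' @param groups Named list of at least three non-empty numeric vectors.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (length(groups) < 3)
    stop("dunn_posthoc needs >= 3 groups", call. = FALSE)
  if (any(lengths(groups) == 0))
    stop("dunn_posthoc needs non-empty groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)            # midranks
  rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_unadjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    out$z[k] <- z
    out$p_unadjusted[k] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adjusted <- if (correction == "bonferroni")
    pmin(1, out$p_unadjusted * n_pairs) else out$p_unadjusted
  out
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact p-value with margins fixed: the sum of hypergeometric
#' point probabilities not exceeding that of the observed table. Wraps
#' [stats::fisher.test()].
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, b, c, d), 2, byrow=TRUE)`.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("table total must be positive", call. = FALSE)
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Mann-Whitney U test
#'
#' U computed from midranks. For small samples (n1 + n2 <= 12) the
#' two-sided p-value is exact by complete enumeration of all group
#' relabelings of the observed pooled values (valid under ties, unlike the
#' classical null distribution); otherwise a normal approximation with tie
#' correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (for the first sample) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney needs non-empty samples", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (N <= 12) {
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2, u_of)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Screen every battery item across the four diagnostic groups
#'
#' Reproduces the item-wise statistical screen: for each item, a
#' Kruskal-Wallis test across PPPD/CDA/UVH/UD on that item's available
#' (non-missing) values; for items significant at `alpha`, Dunn post-hoc
#' comparisons with Bonferroni correction over the six group pairs. The
#' battery shortlist is the set of items with at least one significant
#' adjusted pair. Items with fewer than `min_per_group` observed values in
#' some group are skipped with a warning.
#'
#' @param cohort Cohort data.frame.
#' @param alpha Two-sided significance level (default 0.05).
#' @param items Character vector of item columns (default [screened_items()]
#'   intersected with the cohort's columns).
#' @param min_per_group Minimum non-missing values required per group.
#' @return List with `results` (one row per analysed item: `item`, `H`,
#'   `df`, `p_kw`, `significant_overall`, `n_significant_pairs`),
#'   `pairwise` (Dunn rows for tested items), and `shortlist` (character).
#' @export
compare_all_items <- function(cohort, alpha = 0.05, items = NULL,
                              min_per_group = 2) {
  if (is.null(items))
    items <- intersect(screened_items(), names(cohort))
  groups <- c("PPPD", "CDA", "UVH", "UD")
  res <- list(); pw <- list()
  for (item in items) {
    vals <- lapply(groups, function(g)
      stats::na.omit(cohort[[item]][cohort$diagnosis == g]))
    names(vals) <- groups
    if (any(lengths(vals) < min_per_group)) {
      warning(sprintf("item '%s' skipped: fewer than %d values in some group",
                      item, min_per_group), call. = FALSE)
      next
    }
    kw <- kruskal_wallis(vals)
    row <- data.frame(item = item, H = kw$H, df = kw$df, p_kw = kw$p,
                      significant_overall = kw$p < alpha,
                      n_significant_pairs = 0L, stringsAsFactors = FALSE)
    if (kw$p < alpha) {
      dn <- dunn_posthoc(vals)
      dn$item <- item
      row$n_significant_pairs <- sum(dn$p_adjusted < alpha)
      pw[[item]] <- dn
    }
    res[[item]] <- row
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  pairwise <- if (length(pw)) do.call(rbind, pw) else NULL
  if (!is.null(pairwise)) rownames(pairwise) <- NULL
  shortlist <- results$item[results$significant_overall &
                              results$n_significant_pairs > 0]
  list(results = results, pairwise = pairwise, shortlist = shortlist)
}
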