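# Independent oracles, deliberately implemented by routes the package does
# not use: exhaustive enumeration and explicit pair counting.

# exhaustive permutation p-value for the KW statistic on a tiny fixture
kw_permutation_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(x)
  h_of <- function(assign) kruskal_wallis(split(x, assign))$H
  obs <- h_of(rep(seq_along(groups), sizes))
  count <- 0L; total <- 0L
  idx1 <- utils::combn(N, sizes[1])
  for (i in seq_len(ncol(idx1))) {
    rest1 <- setdiff(seq_len(N), idx1[, i])
    idx2 <- utils::combn(length(rest1), sizes[2])
    for (j in seq_len(ncol(idx2))) {
      assign <- integer(N)
      assign[idx1[, i]] <- 1L
      assign[rest1[idx2[, j]]] <- 2L
      assign[assign == 0L] <- 3L
      total <- total + 1L
      if (h_of(assign) >= obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# full hypergeometric enumeration of the two-sided Fisher p
fisher_enumeration_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p0 <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# pair counting by explicit double loop
auc_pair_counting <- function(scores, labels, orientation = "greater") {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  a <- s / (length(pos) * length(neg))
  if (orientation == "greater") a else 1 - a
}

# brute-force Youden search over every cut between observed scores
youden_brute_force <- function(scores, labels, orientation = "greater") {
  pos <- scores[labels]; neg <- scores[!labels]
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf; best_sens <- NA
  for (t in cuts) {
    if (orientation == "greater") {
      sens <- mean(pos >= t); spec <- mean(neg < t)
    } else {
      sens <- mean(pos < t); spec <- mean(neg >= t)
    }
    j <- sens + spec - 1
    if (j > best + 1e-12 ||
        (abs(j - best) <= 1e-12 && sens > best_sens + 1e-12)) {
      best <- j; best_sens <- sens
    }
  }
  list(J = best, sensitivity = best_sens)
}
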