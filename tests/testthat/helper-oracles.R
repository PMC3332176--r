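# Independent brute-force oracles used by the tests. None of these call
# into the package's own implementation paths.

# pairwise Mann-Whitney AUC: P(score_lesion > score_skin) + P(tie)/2,
# enumerated over all lesion-skin pixel pairs
mann_whitney_auc <- function(score, gt) {
  s <- as.numeric(score)
  g <- as.numeric(gt) == 1
  pos <- s[g]; neg <- s[!g]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# globally optimal 2-cluster partition by enumeration of all assignments
exhaustive_kmeans2 <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    w <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    if (w < best) best <- w
  }
  best
}

# Mamdani max-min inference evaluated with plain loops over rules and the
# candidate grid, from the raw set parameters
brute_force_infer <- function(D, size, rulebase, candidates = 2:40) {
  gm <- function(x, set) exp(-(x - set$center)^2 / (2 * set$spread^2))
  best_q <- -Inf; best_c <- candidates[1L]
  for (cc in candidates) {
    q <- 0
    for (i in seq_len(nrow(rulebase$rules))) {
      r <- rulebase$rules[i, ]
      fire <- min(gm(D, rulebase$distance_sets[[r$distance]]),
                  gm(size, rulebase$size_sets[[r$size]]))
      q <- max(q, min(fire, gm(cc, rulebase$cluster_sets[[r$cluster]])))
    }
    if (q > best_q) { best_q <- q; best_c <- cc }
  }
  max(2L, best_c)
}

# dyadic-aligned two-level RGB test image: dark rectangle on light ground
two_level_image <- function(n = 32L, lo = 80, hi = 200,
                            rows = 9:24, cols = 7:22) {
  m <- matrix(hi, n, n)
  m[rows, cols] <- lo
  list(image = array(rep(m, 3L), dim = c(n, n, 3L)),
       gt = (m == lo) * 1L)
}
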