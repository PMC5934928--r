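# Independent oracles used across tests: brute-force, expansion-sort and
# Monte-Carlo re-derivations of the Svensson measures, kept deliberately
# separate from the package's computational paths.

# random paired table with C categories and n pairs
random_table <- function(C = sample(2:6, 1), n = sample(5:50, 1)) {
  p <- stats::rexp(C * C)
  counts <- matrix(as.vector(stats::rmultinom(1, n, p)), C, C)
  paired_table(counts, seq_len(C))
}

# RP by explicit double loop over category pairs
rp_oracle <- function(tab) {
  m <- marginal_distributions(tab)
  C <- length(m$p1)
  s <- 0
  for (i in seq_len(C))
    for (j in seq_len(C))
      s <- s + m$p1[[i]] * m$p2[[j]] * sign(j - i)
  s
}

# augmented mean ranks by expanding to individual observations and ranking
# with lexicographic keys (mid-ranks via average ties)
rank_oracle <- function(tab) {
  cnt <- tab$counts
  C <- nrow(cnt)
  idx <- which(cnt > 0, arr.ind = TRUE)
  i <- rep(idx[, 1], cnt[idx])
  j <- rep(idx[, 2], cnt[idx])
  r1 <- rank(i * (C + 1) + j)   # occasion-1 primary, occasion-2 ties
  r2 <- rank(j * (C + 1) + i)
  key <- paste(i, j)
  list(i = i, j = j,
       rbar1 = tapply(r1, key, mean), rbar2 = tapply(r2, key, mean),
       key = key)
}

# RV from the expansion-sort oracle's cell mean ranks
rv_oracle <- function(tab) {
  o <- rank_oracle(tab)
  w <- tapply(rep(1, length(o$i)), o$key, length)
  n <- tab$n
  6 / n^3 * sum(w * (o$rbar1 - o$rbar2)^2)
}

# RC by Monte-Carlo triple draws from the estimated marginals
rc_mc_oracle <- function(tab, draws = 1e6, kappa = 4) {
  m <- marginal_distributions(tab)
  draw <- function(p) pmin(findInterval(stats::runif(draws), cumsum(p)) + 1,
                           length(p))
  x1 <- draw(m$p1); x2 <- draw(m$p1)
  y1 <- draw(m$p2); y2 <- draw(m$p2)
  c21 <- mean(x1 < y1 & y1 < x2)
  c12 <- mean(y1 < x1 & x1 < y2)
  kappa * (c21 - c12)
}

# bootstrap SE of RP by multinomial resampling of the table
boot_se_rp <- function(tab, B = 1e4) {
  cnt <- tab$counts
  C <- nrow(cnt)
  reps <- stats::rmultinom(B, tab$n, as.vector(cnt))
  stats::sd(apply(reps, 2, function(v)
    relative_position(paired_table(matrix(v, C, C), tab$categories))))
}

# merge adjacent categories c and c+1 of a paired table (both margins)
merge_categories <- function(tab, c) {
  cnt <- tab$counts
  cnt[c, ] <- cnt[c, ] + cnt[c + 1, ]
  cnt <- cnt[-(c + 1), , drop = FALSE]
  cnt[, c] <- cnt[, c] + cnt[, c + 1]
  cnt <- cnt[, -(c + 1), drop = FALSE]
  paired_table(cnt, seq_len(nrow(cnt)))
}

# simulate two ordinal items discretising a bivariate normal with corr rho
simulate_bvn_ordinal <- function(n, rho, tau1, tau2) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(findInterval(x, tau1) + 1, findInterval(y, tau2) + 1)
}

# a complete raw RAND-36 record at the given response for every item
uniform_record <- function(pick = c("best", "worst")) {
  pick <- match.arg(pick)
  recode <- rand36_recode_table()
  vapply(1:36, function(i) {
    s <- recode[recode$item == i, ]
    s$raw[if (pick == "best") which.max(s$score) else which.min(s$score)]
  }, numeric(1))
}
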