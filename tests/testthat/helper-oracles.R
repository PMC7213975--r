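## Independent oracles used across the suite. These deliberately avoid the
## package's code paths: ranks are computed by counting, statistics from
## the textbook formulas, velocities by plain unwrap-then-diff.

## counting-based midranks: rank = #(smaller) + (#(equal) + 1) / 2
oracle_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

## Kruskal-Wallis H via the rank-sum form with tie correction
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- oracle_ranks(x)
  Rsum <- tapply(r, g, sum)
  n_i <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n_i) - 3 * (N + 1)
  tt <- table(x)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr == 0) return(0)
  H / corr
}

## Dunn z for one group vs control from first principles
oracle_dunn_z <- function(groups, lab, control) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- oracle_ranks(x)
  Rbar_a <- mean(r[g == lab]); Rbar_c <- mean(r[g == control])
  n_a <- sum(g == lab); n_c <- sum(g == control)
  tt <- table(x)
  s2 <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  se <- sqrt(s2 * (1 / n_a + 1 / n_c))
  if (se == 0) 0 else (Rbar_a - Rbar_c) / se
}

## brute-force isolation distance: explicit inverse, per-point quadratic
## form, full sort
oracle_isolation_distance <- function(cluster, noise) {
  mu <- colMeans(cluster)
  Sinv <- solve(cov(cluster))
  d2 <- apply(noise, 1, function(p) {
    v <- p - mu
    as.numeric(t(v) %*% Sinv %*% v)
  })
  sort(d2)[nrow(cluster)]
}

## unwrap-then-differentiate velocity oracle (forward differences)
oracle_velocity <- function(t, angle, diameter) {
  d <- diff(angle)
  d <- d - 2 * pi * round(d / (2 * pi))
  arc <- c(0, cumsum(d)) * diameter / 2
  diff(arc) / diff(t)
}

## exhaustive single-split change-point search minimizing two-segment SSE
oracle_single_split <- function(x) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  costs <- vapply(1:(n - 1), function(k) sse(x[1:k]) + sse(x[(k + 1):n]),
                  numeric(1))
  which.min(costs)
}

## onset-matching F1 at a time tolerance (greedy one-to-one matching)
onset_f1 <- function(detected, truth, tol = 0.5) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (o in truth) {
    d <- abs(detected - o)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  prec <- if (length(detected)) tp / length(detected) else 0
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

## linear-interpolation quantile from a full sort (five-number oracle)
oracle_boxstats <- function(x) {
  x <- sort(x)
  n <- length(x)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  c(min = x[1], q1 = q(0.25), median = q(0.5), q3 = q(0.75), max = x[n])
}

## shared tiny-session builder for pipeline-level tests
make_tiny_spec <- function(seed, vip_gamma = 0.7, vip_mi = 0.3) {
  groups <- data.frame(label = c("CON", "VIP", "PV", "SST"),
                       n = c(12L, 6L, 6L, 8L))
  eff <- data.frame(label = c("CON", "VIP", "PV", "SST"),
                    gamma_amp = c(1, vip_gamma, 1, 1),
                    fr_mult = 1,
                    mi_mult = c(1, vip_mi, 1, 1),
                    soc_pref = 0.35, marble_p = 0.6,
                    mortality_hazard = 5e-4, seizure_hazard = 5e-4)
  cohort_spec(groups, eff, control_label = "CON", seed = seed)
}
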