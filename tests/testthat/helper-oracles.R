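# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms: equilibria are found by bisection on the
# mass-action balance, p-values by direct enumeration, quantiles by a
# hand-written sort-and-interpolate.

# complex concentration solving KD*DR = D_free*(R - DR) by bisection on [0, R]
oracle_occupancy <- function(d_free, r_total, kd, iter = 80) {
  vapply(seq_along(d_free), function(i) {
    lo <- 0; hi <- r_total[i]
    f <- function(dr) kd[i] * dr - d_free[i] * (r_total[i] - dr)
    for (k in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# free ligand D solving D + occupancy-balance complex = T, bisection on [0, T]
oracle_free_ligand <- function(t_total, r_total, kd, iter = 80) {
  vapply(seq_along(t_total), function(i) {
    lo <- 0; hi <- t_total[i]
    g <- function(d) d + d * r_total[i] / (kd[i] + d) - t_total[i]
    for (k in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# exact two-sided Mann-Whitney p by enumerating every split of the pooled
# values; U counted directly from pairwise comparisons, not rank sums
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    xa <- pooled[idx]; xb <- pooled[-idx]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# linear-interpolation quantile between order statistics, written from the
# definition: h = (n-1)p + 1, interpolate x_(floor(h)) .. x_(floor(h)+1)
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(xs[n])
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }, numeric(1))
}

# small model-consistent cohort for round-trip tests
make_mechanistic_cohort <- function(n = 20, group = "aflp", kd = 50,
                                    noise_cv = 0, seed = 123) {
  simulate_group(group, n, mode = "mechanistic_from_free", kd = kd,
                 noise_cv = noise_cv, seed = seed)
}
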