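# Independent reference implementations used to cross-check the package.

# Exhaustive optimal-partitioning dynamic program for piecewise-constant
# mean with squared-error cost (no pruning); O(n^2).
op_changepoints_dp <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(integer(0))
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x * x))
  f <- c(-penalty, rep(Inf, n))
  back <- integer(n)
  for (t in seq_len(n)) {
    s <- seq_len(t)
    cost <- S2[t + 1] - S2[s] - (S1[t + 1] - S1[s])^2 / (t - s + 1)
    total <- f[s] + cost + penalty
    best <- which.min(total)
    f[t + 1] <- total[best]
    back[t] <- best - 1L
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    cps <- c(back[t], cps)
    t <- back[t]
  }
  as.integer(cps[cps > 0])
}

# Projected-gradient non-negative least squares: min ||A w - b||, w >= 0.
nnls_pg <- function(A, b, max_iter = 50000, tol = 1e-12) {
  L <- norm(crossprod(A), "2")
  w <- rep(0, ncol(A))
  for (i in seq_len(max_iter)) {
    g <- crossprod(A, A %*% w - b)
    w_new <- pmax(0, w - as.numeric(g) / L)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}

# Forward tumor/normal mixing: absolute profile -> relative profile with
# genome-wide mean relative copy number r_target.
forward_relative_profile <- function(profile, purity, r_target = 1) {
  seg <- as.data.frame(profile)
  mix <- purity * seg$value + 2 * (1 - purity)
  len <- seg$end - seg$start
  seg$value <- mix * r_target / (sum(mix * len) / sum(len))
  cn_profile(seg, attr(profile, "genome"), "relative")
}

# Small deterministic genome + profile builders for hand-constructed cases.
tiny_genome <- function(n = 2, len = 1e7, arm = 0.5) {
  genome_table(paste0("chr", seq_len(n)), rep(len, n), rep(arm * len, n))
}

make_profile <- function(genome, chrom, start, end, value,
                         space = "absolute") {
  cn_profile(data.frame(chrom = chrom, start = start, end = end,
                        value = value), genome, space)
}
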