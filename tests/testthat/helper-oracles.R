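# Fixtures are built in code; oracles here are written from the definitions,
# independent of the implementation paths they check.

# Noise-free normalized data sampled exactly from a 4PL curve.
make_curve_data <- function(curve, concs = 30000 / 3^(9:0), dmso = curve$top) {
  normalized_curve_data(concs, fourpl_response(curve, concs), dmso_level = dmso)
}

# Exact two-sided rank-sum p by enumerating every assignment of the combined
# values to the two groups (distinct values only).
wilcox_exact_oracle <- function(x, y) {
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  n <- length(vals); nx <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(i) u_of(vals[i], vals[-i]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact two-sided Fisher p for a 2x2 table by full hypergeometric enumeration:
# sum of the probabilities of all tables (margins fixed) no more probable than
# the observed one (relative tolerance as in stats::fisher.test).
fisher_exact_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  k <- max(0, r1 - c2):min(r1, c1)
  pr <- stats::dhyper(k, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Brute-force inversion of a 4PL curve over a dense log-spaced grid.
grid_invert_oracle <- function(curve, level, cmin, cmax, n = 1e6) {
  g <- exp(seq(log(cmin), log(cmax), length.out = n))
  g[which.min(abs(fourpl_response(curve, g) - level))]
}
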