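# Independent oracles and small dataset builders used across the suite.

# Loop-written Peto sums, kept deliberately naive and separate from the
# package's vectorized engine.
peto_naive <- function(ds, alpha = 0.05) {
  so <- 0
  sv <- 0
  for (i in seq_len(nrow(ds))) {
    a <- ds$t_cases[i]; c_ <- ds$c_cases[i]
    n1 <- ds$t_n[i]; n2 <- ds$c_n[i]
    N <- n1 + n2
    m1 <- a + c_
    so <- so + (a - m1 * n1 / N)
    sv <- sv + m1 * (N - m1) * n1 * n2 / (N^2 * (N - 1))
  }
  z <- so / sqrt(sv)
  list(log_effect = so / sv, se = 1 / sqrt(sv),
       p_value = 2 * pnorm(-abs(z)))
}

# Beta-binomial log-likelihood written out again, independently of the
# package, for the grid-search oracle: arm counts y ~ BetaBin(n, mu, rho),
# logit(mu) = b0 + b1 * treat, shape a = mu(1-rho)/rho, b = (1-mu)(1-rho)/rho.
bb_loglik_independent <- function(par, y, n, treat) {
  mu <- 1 / (1 + exp(-(par[1] + par[2] * treat)))
  rho <- 1 / (1 + exp(-par[3]))
  s <- (1 - rho) / rho
  sum(lchoose(n, y) + lbeta(y + mu * s, n - y + (1 - mu) * s) -
        lbeta(mu * s, (1 - mu) * s))
}

# Coarse-to-fine grid maximization of the independent likelihood, over the
# same parameter box the model defines (logit(rho) in [-12, 8], coefficients
# in [-15, 15]).
bb_grid_oracle <- function(y, n, treat,
                           center = c(-2, 0, -3), width = c(5, 4, 8),
                           refinements = 7, points = 13) {
  for (r in seq_len(refinements)) {
    grid <- expand.grid(
      b0 = seq(max(center[1] - width[1], -15),
               min(center[1] + width[1], 15), length.out = points),
      b1 = seq(max(center[2] - width[2], -15),
               min(center[2] + width[2], 15), length.out = points),
      lr = seq(max(center[3] - width[3], -12),
               min(center[3] + width[3], 8), length.out = points)
    )
    ll <- apply(grid, 1, bb_loglik_independent, y = y, n = n, treat = treat)
    center <- as.numeric(grid[which.max(ll), ])
    width <- width / (points / 2.5)
  }
  list(par = center, loglik = max(ll))
}

worked_dataset <- function() {
  meta_dataset(data.frame(
    study_id = c("A", "B"),
    t_cases = c(0L, 1L), t_n = c(10L, 50L),
    c_cases = c(0L, 3L), c_n = c(10L, 50L)
  ))
}

# Random valid dataset with a forced number of double-zero studies and at
# least one case elsewhere; independent of the package's generator.
rand_meta <- function(seed, k = 5, n_dz = 1, risk = 0.08, n_lo = 10,
                      n_hi = 80) {
  set.seed(seed)
  n_t <- sample(n_lo:n_hi, k, replace = TRUE)
  n_c <- sample(n_lo:n_hi, k, replace = TRUE)
  t_cases <- rbinom(k, n_t, risk)
  c_cases <- rbinom(k, n_c, risk)
  if (n_dz > 0) {
    t_cases[seq_len(n_dz)] <- 0L
    c_cases[seq_len(n_dz)] <- 0L
  }
  # exactly n_dz double-zero studies: give accidental ones a control case
  if (n_dz < k) {
    extra <- which(t_cases == 0L & c_cases == 0L)
    extra <- setdiff(extra, seq_len(n_dz))
    c_cases[extra] <- 1L
  }
  if (sum(t_cases) + sum(c_cases) == 0) c_cases[k] <- 1L
  meta_dataset(data.frame(
    study_id = sprintf("R%02d", seq_len(k)),
    t_cases = t_cases, t_n = n_t,
    c_cases = c_cases, c_n = n_c
  ))
}

tourniquet_fixture <- function() {
  read_meta_csv(system.file("extdata", "tourniquet_synthetic.csv",
                            package = "hibi"))
}
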