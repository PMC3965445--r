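# Independent oracles used across the test files. These recompute expected
# quantities by routes that share no code with the package implementation.

# Direct-summation sums of squares for the mixed design: 2 groups x n
# subjects x t times, one observation per (subject, time).
oracle_rm_ss <- function(tab) {
  tab$treatment <- factor(tab$treatment)
  tab$time_point <- factor(tab$time_point)
  tab$animal_id <- factor(tab$animal_id)
  g <- levels(tab$treatment); tp <- levels(tab$time_point)
  n <- length(unique(tab$animal_id[tab$treatment == g[1]]))
  t_ <- length(tp)
  grand <- mean(tab$value)
  m_g <- tapply(tab$value, tab$treatment, mean)
  m_t <- tapply(tab$value, tab$time_point, mean)
  m_gt <- tapply(tab$value, list(tab$treatment, tab$time_point), mean)
  m_gs <- tapply(tab$value, tab$animal_id, mean)
  sub_group <- tapply(as.character(tab$treatment), tab$animal_id, `[`, 1)

  ss_treat <- t_ * n * sum((m_g - grand)^2)
  ss_subj <- t_ * sum((m_gs - m_g[sub_group])^2)
  ss_time <- length(g) * n * sum((m_t - grand)^2)
  dev <- m_gt
  for (i in seq_along(g)) for (j in seq_along(tp))
    dev[i, j] <- m_gt[i, j] - m_g[i] - m_t[j] + grand
  ss_inter <- n * sum(dev^2)
  resid <- numeric(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    gi <- as.character(tab$treatment[r]); tj <- as.character(tab$time_point[r])
    resid[r] <- tab$value[r] - m_gt[gi, tj] -
      m_gs[[as.character(tab$animal_id[r])]] + m_g[[gi]]
  }
  ss_werr <- sum(resid^2)
  list(treatment = ss_treat, subjects_error = ss_subj, time = ss_time,
       interaction = ss_inter, within_error = ss_werr,
       df = c(treatment = length(g) - 1,
              subjects_error = length(g) * (n - 1),
              time = t_ - 1,
              interaction = (length(g) - 1) * (t_ - 1),
              within_error = length(g) * (n - 1) * (t_ - 1)))
}

# Direct-summation SS for the fully between-subjects two-way layout.
oracle_between_ss <- function(tab) {
  tab$treatment <- factor(tab$treatment)
  tab$time_point <- factor(tab$time_point)
  g <- levels(tab$treatment); tp <- levels(tab$time_point)
  n <- nrow(tab) / (length(g) * length(tp))
  grand <- mean(tab$value)
  m_g <- tapply(tab$value, tab$treatment, mean)
  m_t <- tapply(tab$value, tab$time_point, mean)
  m_gt <- tapply(tab$value, list(tab$treatment, tab$time_point), mean)
  ss_treat <- n * length(tp) * sum((m_g - grand)^2)
  ss_time <- n * length(g) * sum((m_t - grand)^2)
  dev <- m_gt
  for (i in seq_along(g)) for (j in seq_along(tp))
    dev[i, j] <- m_gt[i, j] - m_g[i] - m_t[j] + grand
  ss_inter <- n * sum(dev^2)
  cellm <- m_gt[cbind(as.character(tab$treatment), as.character(tab$time_point))]
  ss_err <- sum((tab$value - cellm)^2)
  list(treatment = ss_treat, time = ss_time, interaction = ss_inter,
       error = ss_err)
}

# 1D finite-difference Helmholtz oracle: same 3-point discretisation,
# Dirichlet ends (u[1] = amp, u[n] = 0), dense tridiagonal solve.
oracle_solve_1d <- function(G, n, h, omega, amp, sigma = rep(0, n),
                            rho = 1000) {
  A <- matrix(0 + 0i, n - 2, n - 2)
  b <- complex(n - 2)
  for (i in 2:(n - 1)) {
    r <- i - 1
    A[r, r] <- -2 * G / h^2 + rho * omega^2 * (1 - 1i * sigma[i])
    if (r > 1) A[r, r - 1] <- G / h^2 else b[r] <- b[r] - G / h^2 * amp
    if (r < n - 2) A[r, r + 1] <- G / h^2
  }
  c(amp, solve(A, b), 0 + 0i)
}

# Quadratic sponge profile matching solve_forward's ramp on the far edge.
oracle_sponge_profile <- function(n, width, smax) {
  dist_right <- (n - 1) - (0:(n - 1))
  pmax(0, (width - dist_right) / width)^2 * smax
}

# Standard protocol/phantom fixtures at reduced size for fast tests:
# same pixel spacing as the 128 x 25 mm acquisition (12.2 px/wavelength at
# the control hippocampal modulus).
fast_protocol <- function(n = 64) acquisition_protocol(matrix = n, fov = n * 0.025 / 128)

ctrl_gstar <- 4608 + 1388i
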