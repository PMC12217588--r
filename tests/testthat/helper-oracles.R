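# Independent brute-force oracles, deliberately written as naive per-day,
# per-individual loops so they share no code path with the package.

# census oracle: recount n_xj and E_xj day by day
oracle_schedules <- function(cohort) {
  schema <- cohort$schema
  keep <- !cohort$records$excluded
  rec <- cohort$records[keep, , drop = FALSE]
  ent <- cohort$entry[keep, , drop = FALSE]
  eggs <- cohort$eggs[keep, , drop = FALSE]
  n01 <- nrow(rec)
  omega <- max(rec$death_age)
  k <- length(schema$stages)
  n_imm <- schema$first_adult - 1L
  n_xj <- matrix(0, omega + 1L, k)
  E_xj <- matrix(0, omega + 1L, k)
  for (x in 0:omega) {
    for (i in seq_len(n01)) {
      if (x >= rec$death_age[i]) next           # dead
      e <- ent[i, ]
      s <- max(which(!is.na(e) & e <= x))       # current stage slot
      j <- if (s <= n_imm) s
           else if (rec$sex[i] == "F") schema$female_stage
           else schema$male_stage
      n_xj[x + 1L, j] <- n_xj[x + 1L, j] + 1
      if (rec$sex[i] == "F" && ncol(eggs) >= x + 1L && eggs[i, x + 1L] > 0)
        E_xj[x + 1L, j] <- E_xj[x + 1L, j] + eggs[i, x + 1L]
    }
  }
  s_xj <- n_xj / n01
  l_x <- rowSums(s_xj)
  f_xj <- ifelse(n_xj > 0, E_xj / n_xj, 0)
  m_x <- ifelse(l_x > 0, rowSums(s_xj * f_xj) / l_x, 0)
  list(s_xj = s_xj, l_x = l_x, f_xj = f_xj, m_x = m_x,
       n_xj = n_xj, E_xj = E_xj)
}

# fine-grid scan of the Euler-Lotka residual: coarse localisation of the
# sign change, then a 1e-6 grid within the bracketing cell
oracle_euler_grid <- function(l_x, m_x, lo = -0.5, hi = 1.5) {
  phi <- l_x * m_x
  x1 <- seq_along(phi)                 # x + 1
  res <- function(r) vapply(r, function(ri) sum(exp(-ri * x1) * phi) - 1,
                            numeric(1))
  coarse <- seq(lo, hi, by = 1e-3)
  v <- res(coarse)
  i <- which(v[-1] <= 0 & v[-length(v)] > 0)[1]
  fine <- seq(coarse[i], coarse[i + 1], by = 1e-6)
  vf <- res(fine)
  j <- which(vf <= 0)[1]
  fine[j]
}
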