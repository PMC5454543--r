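# Independent oracles used to cross-check the package implementations.
# Each oracle is deliberately coded via a different route than the package
# (different formulation, different library, or brute force).

# ICC oracle: mean squares from stats::aov / anova(lm), then the
# variance-components route (method of moments), not the mean-squares ratio
# form used in the package.
oracle_icc <- function(m, form = "single") {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   row = factor(rep(seq_len(n), times = k)),
                   col = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::lm(y ~ row + col, data = df))
  MSR <- a["row", "Mean Sq"]; MSC <- a["col", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  s2r <- (MSR - MSE) / k
  s2c <- (MSC - MSE) / n
  s2e <- MSE
  if (form == "single") {
    s2r / (s2r + s2c + s2e)
  } else {
    s2r / (s2r + (s2c + s2e) / k)
  }
}

# Friedman oracle: tie-corrected statistic via the sum-of-squares
# formulation n(k-1) * sum((Rbar_j - (k+1)/2)^2) / sum((r_ij - (k+1)/2)^2),
# algebraically equal to the tie-count form but independently derived.
oracle_friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  num <- n * (k - 1) * sum((colMeans(r) - (k + 1) / 2)^2)
  den <- sum((r - (k + 1) / 2)^2) / n
  if (den == 0) return(0)
  num / den
}

# Exhaustive permutation distribution of the Friedman statistic for small
# n x k designs: all (k!)^n relabelings within blocks.
oracle_friedman_perm_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  perms <- perms_of(k)
  obs <- oracle_friedman_stat(m)
  idx <- rep(list(seq_len(nrow(perms))), n)
  grid <- as.matrix(expand.grid(idx))
  stats_all <- apply(grid, 1, function(g) {
    mp <- t(vapply(seq_len(n), function(i) m[i, perms[g[i], ]], numeric(k)))
    oracle_friedman_stat(mp)
  })
  mean(stats_all >= obs - 1e-12)
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perms_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Analytic zero-phase Butterworth amplitude ratio at frequency f for a
# low-pass of given order and cutoff: the forward-backward pass applies the
# squared magnitude |H(f)|^2 = 1 / (1 + (f/fc)^(2*order)).
oracle_butter_amplitude <- function(f, cutoff = 12, order = 2) {
  1 / (1 + (f / cutoff)^(2 * order))
}

# Torque-balance CoP oracle: solve sum(r_i x f_i) = r_cop x F_total for the
# planar CoP given four vertical corner loads at the sensor positions.
oracle_cop_from_loads <- function(TL, TR, BL, BR, span_ml, span_ap) {
  pos <- rbind(  # (ml, ap) sensor coordinates, mm
    TL = c(-span_ml / 2,  span_ap / 2),
    TR = c( span_ml / 2,  span_ap / 2),
    BL = c(-span_ml / 2, -span_ap / 2),
    BR = c( span_ml / 2, -span_ap / 2))
  f <- c(TL, TR, BL, BR)
  Ftot <- sum(f)
  # vertical forces: moment about ap-axis gives ml, about ml-axis gives ap
  ml <- sum(pos[, 1] * f) / Ftot
  ap <- sum(pos[, 2] * f) / Ftot
  c(ap = ap, ml = ml)
}

# Wrench-transport oracle: move the plate moment from its origin to the
# contact surface, M' = M - r x F. Floor-embedded plates use a z-down axis
# with the moment origin below the surface, so the origin-to-surface vector
# is r = (0, 0, -dz): (r x F)_x = dz*Fy, (r x F)_y = -dz*Fx.
oracle_cop_from_wrench <- function(Fx, Fy, Fz, Mx, My, dz_m) {
  Mx_s <- Mx - dz_m * Fy
  My_s <- My + dz_m * Fx
  c(ap = Mx_s / Fz * 1000, ml = -My_s / Fz * 1000)  # mm
}
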