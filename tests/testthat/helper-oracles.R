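# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# Exhaustive log-grid search over K_D with the linear subproblem solved by
# OLS at each grid point, refined around the optimum. Oracle for
# fit_isotherm.
grid_oracle_kd <- function(conc, signal, lo = log10(min(conc[conc > 0]) / 1000),
                           hi = log10(max(conc) * 1000),
                           rounds = 3, n_grid = 60) {
  best <- NULL
  for (k in seq_len(rounds)) {
    lkds <- seq(lo, hi, length.out = n_grid)
    sse <- vapply(lkds, function(l) {
      kd <- 10^l
      sat <- conc / (conc + kd)
      b <- stats::coef(stats::lm(signal ~ sat + conc))
      b[is.na(b)] <- 0
      pred <- b[1] + max(0, b[2]) * sat + max(0, b[3]) * conc
      sum((signal - pred)^2)
    }, numeric(1))
    i <- which.min(sse)
    best <- list(kd = 10^lkds[i], sse = sse[i], lkds = lkds, sse_grid = sse)
    step <- (hi - lo) / (n_grid - 1)
    lo <- lkds[i] - step
    hi <- lkds[i] + step
  }
  best
}

# Horn's quaternion method for optimal superposition RMSD: the maximum
# eigenvalue of the 4x4 key matrix gives the optimal correlation, no
# rotation matrix is ever formed. Oracle for superpose()/rmsd_matrix().
quaternion_rmsd <- function(ref, mob) {
  A <- sweep(mob, 2, colMeans(mob))
  B <- sweep(ref, 2, colMeans(ref))
  S <- crossprod(A, B)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(0, msd))
}

# From-scratch restatement of the greedy clustering rule, recomputing
# neighbor counts with explicit loops at every iteration. Oracle for
# greedy_cluster().
greedy_reference <- function(M, cutoff) {
  n <- nrow(M)
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  while (anyNA(labels)) {
    best_i <- 0L
    best_count <- -1L
    for (i in seq_len(n)) {
      if (!is.na(labels[i])) next
      count <- 0L
      for (j in seq_len(n)) {
        if (is.na(labels[j]) && M[i, j] <= cutoff) count <- count + 1L
      }
      if (count > best_count) { # strict: ties keep the lowest index
        best_count <- count
        best_i <- i
      }
    }
    cl <- cl + 1L
    centers[cl] <- best_i
    for (j in seq_len(n)) {
      if (is.na(labels[j]) && M[best_i, j] <= cutoff) labels[j] <- cl
    }
  }
  list(labels = labels, centers = centers)
}

# Brute-force probe recount with an independent distance routine
# (per-coordinate wrapped differences, explicit loops over frames and
# probes). Oracle for probe_density().
brute_probe_counts <- function(traj, cutoff) {
  probe_idx <- which(traj$atoms$is_probe)
  heavy_idx <- which(!traj$atoms$is_probe & traj$atoms$is_heavy)
  counts <- numeric(length(heavy_idx))
  for (fr in traj$frames) {
    for (pi in probe_idx) {
      for (k in seq_along(heavy_idx)) {
        dd <- 0
        for (dim in 1:3) {
          dx <- abs(fr[pi, dim] - fr[heavy_idx[k], dim])
          if (!is.null(traj$box)) {
            dx <- min(dx, traj$box[dim] - dx)
          }
          dd <- dd + dx * dx
        }
        if (dd <= cutoff^2) counts[k] <- counts[k] + 1
      }
    }
  }
  counts / length(traj$frames)
}

# Two-tailed p from the t density by numerical integration (no pt()).
t_density_p <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf)$value
}

# Exact permutation two-sided p-value over all relabelings of a vs b.
permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  obs <- abs(mean(a) - mean(b))
  deltas <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(deltas >= obs - 1e-12)
}

# Shared toy lineage for variant-level tests.
tiny_variant <- function(aa = c("A", "N", "V", "T", "G"),
                         positions = as.character(seq_along(aa))) {
  vh_variant("toy", positions, aa)
}
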