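# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: scalar loops, explicit formulas, and
# grid/direct searches.

# naive O(N^2) ligand-environment nonbonded energy, scalar loops and
# explicit Lorentz-Berthelot / Coulomb formulas
naive_interaction_energy <- function(charge, sigma, epsilon, xyz,
                                     ligand_idx, env_idx, cutoff = 10,
                                     box = NULL) {
  vdw <- 0; elec <- 0
  for (i in ligand_idx) {
    for (j in env_idx) {
      d <- xyz[i, ] - xyz[j, ]
      if (!is.null(box)) {
        for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      }
      r <- sqrt(d[1]^2 + d[2]^2 + d[3]^2)
      if (r > cutoff) next
      eps <- sqrt(epsilon[i] * epsilon[j])
      sig <- (sigma[i] + sigma[j]) / 2
      vdw <- vdw + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      elec <- elec + 332.0636 * charge[i] * charge[j] / r
    }
  }
  c(vdw = vdw, elec = elec)
}

# rotation matrix from z-y-z Euler angles (radians)
euler_rotation <- function(a, b, g) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# minimum RMSD over rotations by coarse Euler-angle grid search followed by
# local refinement; translation handled by centring both sets
grid_search_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rmsd_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  step <- 15 * pi / 180
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi - step, by = step),
                                b = seq(0, pi, by = step),
                                g = seq(0, 2 * pi - step, by = step)))
  vals <- apply(grid, 1, rmsd_of)
  best <- grid[order(vals)[1:5], , drop = FALSE]
  refined <- apply(best, 1, function(start) {
    stats::optim(start, rmsd_of, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  })
  min(refined)
}

# least-squares LIE fit by direct Nelder-Mead minimisation of the SSE
brute_force_lie_fit <- function(d_vdw, d_elec, dg_exp) {
  sse <- function(p) sum((p[1] * d_vdw + p[2] * d_elec + p[3] - dg_exp)^2)
  fit <- stats::optim(c(0, 0, 0), sse, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
  fit <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
  list(alpha = fit$par[1], beta = fit$par[2], gamma = fit$par[3],
       sse = fit$value)
}

# parametric standard errors of an OLS fit, from first principles
ols_param_se <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  sqrt(diag(s2 * solve(crossprod(X))))
}

# quick four-replica set of AR(1) traces around a common mean
make_replica_set <- function(mean, n_rep = 4, n_frames = 401, seed = 1,
                             component = "vdw", state = "bound",
                             ligand_id = "L01", trace_sd = 2) {
  traces <- lapply(seq_len(n_rep), function(r)
    gen_energy_traces(mean, trace_sd = trace_sd, ar1_phi = 0.9,
                      n_frames = n_frames, dt = 0.01,
                      seed = seed + r, component = component,
                      state = state, replica_id = r, ligand_id = ligand_id))
  replica_set(traces, expected_replicas = n_rep)
}
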