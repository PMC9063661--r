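# Desk-scale pairwise nonbonded energies: 12-6 Lennard-Jones with
# Lorentz-Berthelot combination plus truncated Coulomb, summed over
# ligand x environment pairs. Exists to exercise the energy pipeline on toy
# systems; truncated Coulomb is an approximation to the Ewald treatment a
# production engine would use.

#' Lennard-Jones 12-6 pair energy
#'
#' `4*eps_ij*((sig_ij/r)^12 - (sig_ij/r)^6)` with Lorentz-Berthelot
#' combination: `eps_ij = sqrt(eps_i*eps_j)`, `sig_ij = (sig_i+sig_j)/2`
#' (the Amber-family convention).
#'
#' @param eps_i,eps_j Well depths in kcal/mol, >= 0.
#' @param sig_i,sig_j Collision diameters in Angstrom, > 0.
#' @param r Pair distance in Angstrom, > 0 (vectorised).
#' @return Pair energy in kcal/mol.
#' @export
lj_pair <- function(eps_i, eps_j, sig_i, sig_j, r) {
  if (any(r <= 0)) stop("pair distance must be > 0", call. = FALSE)
  if (any(c(sig_i, sig_j) <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(c(eps_i, eps_j) < 0)) stop("epsilon must be >= 0", call. = FALSE)
  eps <- sqrt(eps_i * eps_j)
  sig <- (sig_i + sig_j) / 2
  sr6 <- (sig / r)^6
  4 * eps * (sr6 * sr6 - sr6)
}

#' Coulomb pair energy
#'
#' `k_e * q_i * q_j / r` with `k_e` = 332.0636 kcal A / (mol e^2).
#'
#' @param q_i,q_j Partial charges in elementary charge units.
#' @param r Pair distance in Angstrom, > 0 (vectorised).
#' @return Pair energy in kcal/mol.
#' @export
coulomb_pair <- function(q_i, q_j, r) {
  if (any(r <= 0)) stop("pair distance must be > 0", call. = FALSE)
  lie_constants[["coulomb_k"]] * q_i * q_j / r
}

#' Build a ligand/environment topology
#'
#' @param charge Per-atom partial charges (e).
#' @param sigma Per-atom LJ collision diameters (Angstrom, > 0).
#' @param epsilon Per-atom LJ well depths (kcal/mol, >= 0).
#' @param ligand_indices,environment_indices Disjoint, non-empty 1-based
#'   index sets partitioning the interacting atoms.
#' @return An object of class `nb_topology`.
#' @export
nb_topology <- function(charge, sigma, epsilon,
                        ligand_indices, environment_indices) {
  n <- length(charge)
  if (length(sigma) != n || length(epsilon) != n)
    stop("charge, sigma, epsilon must have equal length", call. = FALSE)
  if (any(!is.finite(charge)) || any(!is.finite(sigma)) ||
      any(!is.finite(epsilon)))
    stop("atom parameters must be finite", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  li <- as.integer(ligand_indices)
  ei <- as.integer(environment_indices)
  if (length(li) == 0L || length(ei) == 0L)
    stop("ligand and environment index sets must be non-empty", call. = FALSE)
  if (any(li < 1L) || any(li > n) || any(ei < 1L) || any(ei > n))
    stop("atom indices out of bounds", call. = FALSE)
  if (length(intersect(li, ei)))
    stop("ligand and environment index sets must be disjoint", call. = FALSE)
  structure(list(charge = as.numeric(charge), sigma = as.numeric(sigma),
                 epsilon = as.numeric(epsilon),
                 ligand_indices = li, environment_indices = ei,
                 n_atoms = n),
            class = "nb_topology")
}

#' Read a topology from CSV
#'
#' Layout: `index,charge_e,sigma_A,epsilon_kcal,group` with
#' `group` in `{ligand, environment}`; rows are ordered by `index`.
#'
#' @param path CSV path.
#' @return An [nb_topology()].
#' @export
read_topology_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "charge_e", "sigma_A", "epsilon_kcal", "group")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  df <- df[order(df$index), , drop = FALSE]
  if (!all(df$group %in% c("ligand", "environment")))
    stop("group must be 'ligand' or 'environment'", call. = FALSE)
  nb_topology(charge = df$charge_e, sigma = df$sigma_A,
              epsilon = df$epsilon_kcal,
              ligand_indices = which(df$group == "ligand"),
              environment_indices = which(df$group == "environment"))
}

#' A coordinate frame
#'
#' @param coordinates n x 3 numeric matrix of positions in Angstrom.
#' @param box Optional orthorhombic box lengths (length-3, Angstrom); when
#'   present, minimum-image distances are used and each box length must
#'   exceed twice the interaction cutoff.
#' @param time Frame time in ns.
#' @return An object of class `nb_frame`.
#' @export
nb_frame <- function(coordinates, box = NULL, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L || !is.numeric(coordinates) ||
      any(!is.finite(coordinates)))
    stop("coordinates must be a finite n x 3 matrix", call. = FALSE)
  if (!is.null(box)) {
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive lengths", call. = FALSE)
    box <- as.numeric(box)
  }
  structure(list(coordinates = unname(coordinates), box = box,
                 time = as.numeric(time)),
            class = "nb_frame")
}

# minimum-image pairwise distances between two coordinate blocks
.pair_distances <- function(a, b, box = NULL) {
  dx <- outer(a[, 1L], b[, 1L], `-`)
  dy <- outer(a[, 2L], b[, 2L], `-`)
  dz <- outer(a[, 3L], b[, 3L], `-`)
  if (!is.null(box)) {
    dx <- dx - box[1L] * round(dx / box[1L])
    dy <- dy - box[2L] * round(dy / box[2L])
    dz <- dz - box[3L] * round(dz / box[3L])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Ligand-environment interaction energy of one frame
#'
#' Sums [lj_pair()] and [coulomb_pair()] over every ligand x environment
#' atom pair with distance at or below the cutoff (hard truncation, no
#' switching). Intra-ligand and intra-environment pairs never contribute;
#' with a periodic box, minimum-image distances are used.
#'
#' @param topology An [nb_topology()].
#' @param frame An [nb_frame()] with one coordinate triple per topology atom.
#' @param cutoff Interaction cutoff in Angstrom (default 10, i.e. 1.0 nm).
#' @return Named numeric vector `c(vdw, elec)` in kcal/mol.
#' @export
interaction_energy <- function(topology, frame, cutoff = 10) {
  stopifnot(inherits(topology, "nb_topology"), inherits(frame, "nb_frame"))
  .check_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (nrow(frame$coordinates) != topology$n_atoms)
    stop(sprintf("frame has %d atoms, topology %d",
                 nrow(frame$coordinates), topology$n_atoms), call. = FALSE)
  if (!is.null(frame$box) && any(frame$box <= 2 * cutoff))
    stop("each box length must exceed twice the cutoff", call. = FALSE)
  li <- topology$ligand_indices
  ei <- topology$environment_indices
  r <- .pair_distances(frame$coordinates[li, , drop = FALSE],
                       frame$coordinates[ei, , drop = FALSE], frame$box)
  if (any(r < 1e-6)) {
    bad <- which(r < 1e-6, arr.ind = TRUE)[1L, ]
    stop(sprintf("overlapping atoms: ligand atom %d and environment atom %d (r = %.2e A)",
                 li[bad[1L]], ei[bad[2L]], r[bad[1L], bad[2L]]),
         call. = FALSE)
  }
  within <- r <= cutoff
  if (!any(within)) return(c(vdw = 0, elec = 0))
  idx <- which(within, arr.ind = TRUE)
  i <- li[idx[, 1L]]
  j <- ei[idx[, 2L]]
  rij <- r[within]
  vdw <- sum(lj_pair(topology$epsilon[i], topology$epsilon[j],
                     topology$sigma[i], topology$sigma[j], rij))
  elec <- sum(coulomb_pair(topology$charge[i], topology$charge[j], rij))
  c(vdw = vdw, elec = elec)
}

#' Interaction-energy traces along a trajectory
#'
#' Evaluates [interaction_energy()] for every frame and packages the two
#' components as [energy_trace()] objects, bridging the coordinate-level
#' kernel to the averaging/LIE machinery.
#'
#' @inheritParams interaction_energy
#' @param frames List of [nb_frame()] objects with strictly increasing
#'   times.
#' @param state `"bound"` or `"free"` label for the resulting traces.
#' @param ligand_id,replica_id Trace metadata.
#' @return List with elements `vdw` and `elec`, each an [energy_trace()].
#' @export
trajectory_energy_series <- function(topology, frames, cutoff = 10,
                                     state = "bound", ligand_id = "ligand",
                                     replica_id = 1L) {
  if (inherits(frames, "nb_frame")) frames <- list(frames)
  if (length(frames) < 1L) stop("need at least one frame", call. = FALSE)
  energies <- matrix(NA_real_, nrow = length(frames), ncol = 2L)
  times <- numeric(length(frames))
  for (k in seq_along(frames)) {
    e <- tryCatch(interaction_energy(topology, frames[[k]], cutoff),
                  error = function(err)
                    stop(sprintf("frame %d: %s", k, conditionMessage(err)),
                         call. = FALSE))
    energies[k, ] <- e
    times[k] <- frames[[k]]$time
  }
  list(
    vdw = energy_trace(times, energies[, 1L], "vdw", state,
                       replica_id, ligand_id),
    elec = energy_trace(times, energies[, 2L], "elec", state,
                        replica_id, ligand_id)
  )
}
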