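# Structure-level analyses: PDB input (via bio3d), Kabsch superposition and
# C-alpha RMSD series, geometric hydrogen-bond detection, and hydrophobic
# non-bonded contact (NBC) counting at the ligand-peptide interface.

.WATER_RESIDUES <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "SPC", "DOD")
.ION_RESIDUES <- c("NA", "CL", "K", "MG", "CA", "ZN", "NA+", "CL-", "BR",
                   "IOD", "CS", "LI", "RB", "F")

# element symbol from a PDB atom name when no element column is available;
# names like "1HB2" carry leading digits, two-letter elements are rare in
# organic ligands so the first alphabetic character is used
.element_from_name <- function(name) {
  stripped <- sub("^[0-9']+", "", trimws(name))
  toupper(substr(stripped, 1L, 1L))
}

#' Construct a molecular structure
#'
#' A light container for one model's atoms: identity, residue bookkeeping,
#' coordinates in Angstrom, and an interface group label
#' (`peptide` / `ligand` / `other`) driving the hydrogen-bond, contact and
#' RMSD analyses.
#'
#' @param atoms Data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain`, `x`, `y`, `z`, `group`; serials must be
#'   unique and coordinates finite.
#' @param model_id Integer model number (frame index for trajectories).
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, model_id = 1L) {
  need <- c("serial", "name", "element", "res_name", "res_seq", "chain",
            "x", "y", "z", "group")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop(sprintf("atoms table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(atoms) < 1L) stop("structure has zero atoms", call. = FALSE)
  if (anyDuplicated(atoms$serial))
    stop("duplicated atom serials within a model", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop("coordinates must be finite", call. = FALSE)
  if (!all(atoms$group %in% c("peptide", "ligand", "other")))
    stop("group must be 'peptide', 'ligand' or 'other'", call. = FALSE)
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 model_id = as.integer(model_id)),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  tab <- table(x$atoms$group)
  cat(sprintf("<mol_structure> model %d: %d atoms (%s)\n",
              x$model_id, nrow(x$atoms),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

.structure_xyz <- function(s, subset = NULL) {
  a <- if (is.null(subset)) s$atoms else s$atoms[subset, , drop = FALSE]
  unname(as.matrix(a[, c("x", "y", "z")]))
}

#' Read structures from a PDB file
#'
#' Parses `ATOM`/`HETATM` records (fixed-width, via bio3d); a multi-MODEL
#' file yields one structure per model, treated downstream as a trajectory
#' with the frame index as time. Atoms are classified for interface
#' analysis: protein `ATOM` records become `peptide`, non-water `HETATM`
#' records become `ligand`, and waters/counter-ions become `other`.
#' Alternate locations other than blank or `A` are dropped.
#'
#' @param path PDB file path.
#' @return List of [mol_structure()] objects, one per model.
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  if (nrow(atoms) == 0L) stop(sprintf("%s: zero atoms", path), call. = FALSE)
  keep <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
  atoms <- atoms[keep, , drop = FALSE]
  xyz_keep <- which(keep)
  res_up <- toupper(trimws(atoms$resid))
  group <- ifelse(atoms$type == "HETATM",
                  ifelse(res_up %in% c(.WATER_RESIDUES, .ION_RESIDUES),
                         "other", "ligand"),
                  ifelse(res_up %in% .WATER_RESIDUES, "other", "peptide"))
  element <- ifelse(!is.na(atoms$elesy) & nzchar(trimws(atoms$elesy)),
                    toupper(trimws(atoms$elesy)),
                    .element_from_name(atoms$elety))
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)[xyz_keep, ,
                                                         drop = FALSE]
    mol_structure(data.frame(
      serial = atoms$eleno, name = trimws(atoms$elety), element = element,
      res_name = res_up, res_seq = atoms$resno,
      chain = ifelse(is.na(atoms$chain), "A", atoms$chain),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      group = group, stringsAsFactors = FALSE), model_id = m)
  })
}

#' Write structures to a (multi-model) PDB file
#'
#' @param structures A [mol_structure()] or list of them sharing one atom
#'   table (a trajectory); written as `MODEL`/`ENDMDL` blocks when more
#'   than one.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structures, path) {
  if (inherits(structures, "mol_structure")) structures <- list(structures)
  a <- structures[[1L]]$atoms
  # peptide -> ATOM; ligands, waters and ions -> HETATM
  rec <- ifelse(a$group == "peptide", "ATOM", "HETATM")
  # short atom names start in column 14 by PDB convention
  name4 <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  multi <- length(structures) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(structures)) {
    xyz <- .structure_xyz(structures[[m]])
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial, name4, a$res_name, a$chain, a$res_seq,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (determinant +1) and translation minimising
#' the RMSD of `mobile` onto `reference`, by singular value decomposition
#' of the cross-covariance of the centred point sets.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3), row-matched.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   aligned coordinates are `mobile %*% t(rotation) + translation`), and
#'   `rmsd` in Angstrom after alignment.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be matching n x 3 matrices",
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  if (qr(Q)$rank < 2L)
    stop("degenerate (collinear) reference geometry", call. = FALSE)
  H <- crossprod(P, Q)                       # 3 x 3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

.ca_xyz <- function(s) {
  idx <- which(s$atoms$group == "peptide" & s$atoms$name == "CA")
  if (length(idx) == 0L)
    stop("no peptide CA atoms in structure", call. = FALSE)
  .structure_xyz(s, idx)
}

#' C-alpha RMSD along a trajectory
#'
#' Per-frame Kabsch-aligned RMSD of the peptide C-alpha atoms against a
#' reference frame (the initial configuration by default). Aligning before
#' measuring separates internal deformation from rigid-body drift.
#'
#' @param frames List of [mol_structure()] objects with identical CA sets.
#' @param reference_model Index of the reference frame (default 1).
#' @return Data.frame `frame,rmsd_A`.
#' @export
ca_rmsd_series <- function(frames, reference_model = 1L) {
  if (inherits(frames, "mol_structure")) frames <- list(frames)
  if (length(frames) < 1L) stop("no frames", call. = FALSE)
  if (reference_model < 1L || reference_model > length(frames))
    stop("reference_model out of range", call. = FALSE)
  ref <- .ca_xyz(frames[[reference_model]])
  rmsd <- vapply(frames, function(s) {
    xyz <- .ca_xyz(s)
    if (nrow(xyz) != nrow(ref))
      stop("frames carry unequal CA sets", call. = FALSE)
    kabsch_superpose(xyz, ref)$rmsd
  }, numeric(1L))
  data.frame(frame = seq_along(frames), rmsd_A = rmsd)
}

# assign each hydrogen to its covalent donor-capable heavy atom: the
# nearest N/O/S within 1.2 A; unassigned hydrogens are ignored
.assign_hydrogens <- function(atoms, xyz) {
  h_idx <- which(atoms$element == "H")
  heavy_idx <- which(atoms$element %in% c("N", "O", "S"))
  if (length(h_idx) == 0L || length(heavy_idx) == 0L)
    return(data.frame(h = integer(0), donor = integer(0)))
  d <- .pair_distances(xyz[h_idx, , drop = FALSE],
                       xyz[heavy_idx, , drop = FALSE])
  nearest <- apply(d, 1L, which.min)
  dist_min <- d[cbind(seq_along(h_idx), nearest)]
  ok <- dist_min <= 1.2
  data.frame(h = h_idx[ok], donor = heavy_idx[nearest[ok]])
}

#' Detect interface hydrogen bonds by geometric criteria
#'
#' A hydrogen bond requires a donor-acceptor distance strictly below
#' `max_da` and an acceptor-hydrogen-donor angle strictly above
#' `min_angle`. Donors are N/O/S heavy atoms carrying at least one covalent
#' hydrogen (hydrogens are attached to the nearest N/O/S within 1.2 A);
#' acceptors are N/O atoms. Only ligand-peptide pairs are scanned, in both
#' donor directions; intra-molecular pairs are excluded, as are waters and
#' ions.
#'
#' @param s A [mol_structure()] containing explicit hydrogens.
#' @param max_da Donor-acceptor distance gate in Angstrom (default 3.5).
#' @param min_angle A-H-D angle gate in degrees (default 135).
#' @return Data.frame `donor_idx,h_idx,acceptor_idx,distance_A,angle_deg`
#'   (row indices into `s$atoms`), zero rows when no bond qualifies.
#' @export
detect_hbonds <- function(s, max_da = 3.5, min_angle = 135) {
  stopifnot(inherits(s, "mol_structure"))
  atoms <- s$atoms
  xyz <- .structure_xyz(s)
  if (!any(atoms$element == "H"))
    stop("structure has no hydrogens; the geometric criterion needs explicit H",
         call. = FALSE)
  hb <- .assign_hydrogens(atoms, xyz)
  empty <- data.frame(donor_idx = integer(0), h_idx = integer(0),
                      acceptor_idx = integer(0), distance_A = numeric(0),
                      angle_deg = numeric(0))
  if (nrow(hb) == 0L) return(empty)
  acceptors <- which(atoms$element %in% c("N", "O") &
                       atoms$group %in% c("ligand", "peptide"))
  out <- list()
  for (k in seq_len(nrow(hb))) {
    d_idx <- hb$donor[k]; h_idx <- hb$h[k]
    if (!atoms$group[d_idx] %in% c("ligand", "peptide")) next
    # cross-interface acceptors only
    acc <- acceptors[atoms$group[acceptors] != atoms$group[d_idx]]
    if (length(acc) == 0L) next
    da <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d_idx, ])^2))
    cand <- acc[da < max_da]
    if (length(cand) == 0L) next
    da <- da[da < max_da]
    v1 <- t(xyz[cand, , drop = FALSE]) - xyz[h_idx, ]   # H -> A
    v2 <- xyz[d_idx, ] - xyz[h_idx, ]                   # H -> D
    cosang <- colSums(v1 * v2) /
      (sqrt(colSums(v1 * v1)) * sqrt(sum(v2 * v2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang > min_angle
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        donor_idx = d_idx, h_idx = h_idx, acceptor_idx = cand[ok],
        distance_A = da[ok], angle_deg = ang[ok])
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Count hydrophobic non-bonded contacts
#'
#' A non-bonded contact is a ligand carbon or sulfur atom within
#' `range_A[1]` to `range_A[2]` (closed interval, default 2.9-3.9 A) of any
#' peptide atom; each qualifying (ligand atom, peptide atom) pair counts
#' once.
#'
#' @param s A [mol_structure()] with ligand and peptide groups present.
#' @param range_A Closed distance interval in Angstrom.
#' @return List with `n` (contact count) and `pairs`, a data.frame
#'   `ligand_atom,peptide_atom,residue,distance_A`.
#' @export
count_nbc <- function(s, range_A = c(2.9, 3.9)) {
  stopifnot(inherits(s, "mol_structure"))
  atoms <- s$atoms
  lig <- which(atoms$group == "ligand" & atoms$element %in% c("C", "S"))
  pep <- which(atoms$group == "peptide")
  if (sum(atoms$group == "ligand") == 0L)
    stop("structure has no ligand atoms", call. = FALSE)
  empty <- data.frame(ligand_atom = character(0), peptide_atom = character(0),
                      residue = character(0), distance_A = numeric(0))
  if (length(lig) == 0L || length(pep) == 0L) return(list(n = 0L, pairs = empty))
  xyz <- .structure_xyz(s)
  d <- .pair_distances(xyz[lig, , drop = FALSE], xyz[pep, , drop = FALSE])
  hit <- which(d >= range_A[1L] & d <= range_A[2L], arr.ind = TRUE)
  if (nrow(hit) == 0L) return(list(n = 0L, pairs = empty))
  li <- lig[hit[, 1L]]; pi_ <- pep[hit[, 2L]]
  pairs <- data.frame(
    ligand_atom = atoms$name[li],
    peptide_atom = atoms$name[pi_],
    residue = sprintf("%s%d", atoms$res_name[pi_], atoms$res_seq[pi_]),
    distance_A = d[hit])
  list(n = nrow(pairs), pairs = pairs[order(pairs$distance_A), , drop = FALSE])
}

#' Replica-averaged hydrogen-bond count
#'
#' Averages per-frame counts within each replica, then across replicas with
#' equal weight — the same aggregation convention as [replica_average()].
#'
#' @param replicas List of numeric vectors, one per replica, holding
#'   per-frame hydrogen-bond counts.
#' @return Mean count.
#' @export
hbond_replica_average <- function(replicas) {
  if (is.numeric(replicas)) replicas <- list(replicas)
  if (length(replicas) == 0L) stop("no replicas", call. = FALSE)
  if (any(lengths(replicas) == 0L))
    stop("every replica needs at least one frame", call. = FALSE)
  mean(vapply(replicas, mean, numeric(1L)))
}
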