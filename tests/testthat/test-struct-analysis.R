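# compact constructor for hand-built test structures
atom_row <- function(serial, name, element, x, y, z, group,
                     res_name = if (group == "ligand") "LIG" else "ALA",
                     res_seq = if (group == "ligand") 900L else 1L) {
  data.frame(serial = serial, name = name, element = element,
             res_name = res_name, res_seq = res_seq, chain = "A",
             x = x, y = y, z = z, group = group, stringsAsFactors = FALSE)
}

test_that("mol_structure enforces unique serials and finite coordinates", {
  a <- rbind(atom_row(1, "O", "O", 0, 0, 0, "peptide"),
             atom_row(1, "C1", "C", 1, 0, 0, "ligand"))
  expect_error(mol_structure(a), "duplicated")
  b <- atom_row(1, "O", "O", NA, 0, 0, "peptide")
  expect_error(mol_structure(b), "finite")
  expect_error(mol_structure(atom_row(1, "O", "O", 0, 0, 0, "peptide")[0, ]),
               "zero atoms")
})

test_that("PDB round trip preserves models, groups, and coordinates", {
  toy <- gen_toy_complex(10, 3, "contact", n_frames = 2, jitter_A = 0.3,
                         seed = 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy$structures, f)
  back <- read_structure_pdb(f)
  expect_length(back, 2)
  expect_equal(vapply(back, `[[`, integer(1), "model_id"), 1:2)
  for (m in 1:2) {
    orig <- toy$structures[[m]]$atoms
    got <- back[[m]]$atoms
    expect_equal(nrow(got), nrow(orig))
    expect_equal(got$group, orig$group)   # HETATM LIG -> ligand, ATOM -> peptide
    # PDB stores 3 decimals, so agreement is to 1e-3 A in absolute terms
    expect_lt(max(abs(got$x - orig$x)), 1e-3)
    expect_lt(max(abs(got$y - orig$y)), 1e-3)
    expect_lt(max(abs(got$z - orig$z)), 1e-3)
  }
})

test_that("waters and ions are classified as neither peptide nor ligand", {
  a <- rbind(atom_row(1, "CA", "C", 0, 0, 0, "peptide"),
             atom_row(2, "C1", "C", 3, 0, 0, "ligand"),
             atom_row(3, "O", "O", 8, 0, 0, "other", res_name = "HOH",
                      res_seq = 500L),
             atom_row(4, "NA", "NA", 9, 0, 0, "other", res_name = "NA",
                      res_seq = 600L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(mol_structure(a), f)
  s <- read_structure_pdb(f)[[1]]
  expect_equal(s$atoms$group, c("peptide", "ligand", "other", "other"))
})

test_that("kabsch_superpose removes rigid motions exactly", {
  set.seed(71)
  ref <- matrix(rnorm(30, sd = 4), ncol = 3)
  out <- kabsch_superpose(ref, ref)
  expect_equal(out$rmsd, 0, tolerance = 1e-12)
  expect_equal(out$rotation, diag(3), tolerance = 1e-9)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mobile <- ref %*% t(Rz) + matrix(rep(c(5, -3, 11), each = 10), ncol = 3)
  out2 <- kabsch_superpose(mobile, ref)
  expect_equal(out2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(out2$rotation), 1, tolerance = 1e-9)
  aligned <- mobile %*% t(out2$rotation) +
    matrix(rep(out2$translation, each = 10), ncol = 3)
  expect_equal(aligned, ref, tolerance = 1e-9)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch RMSD is invariant under any proper rigid motion", {
  set.seed(72)
  ref <- matrix(rnorm(45, sd = 3), ncol = 3)
  mobile <- ref + matrix(rnorm(45, sd = 0.4), ncol = 3)
  base <- kabsch_superpose(mobile, ref)$rmsd
  for (i in 1:5) {
    ang <- runif(3, 0, 2 * pi)
    R <- euler_rotation(ang[1], ang[2], ang[3])
    moved <- mobile %*% t(R) + matrix(rep(runif(3, -20, 20), each = 15),
                                      ncol = 3)
    expect_equal(kabsch_superpose(moved, ref)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("kabsch_superpose matches an Euler-grid rotation search", {
  set.seed(73)
  for (trial in 1:3) {
    ref <- matrix(rnorm(30, sd = 3), ncol = 3)
    mobile <- ref + matrix(rnorm(30, sd = 0.5), ncol = 3)
    expect_equal(kabsch_superpose(mobile, ref)$rmsd,
                 grid_search_min_rmsd(mobile, ref), tolerance = 1e-3)
  }
})

test_that("ca_rmsd_series is zero for identical or translated frames", {
  toy <- gen_toy_complex(16, 3, "contact", n_frames = 3, seed = 31)
  out <- ca_rmsd_series(toy$structures)
  expect_equal(out$rmsd_A, rep(0, 3), tolerance = 1e-9)

  shifted <- toy$structures
  shifted[[2]]$atoms$x <- shifted[[2]]$atoms$x + 25
  expect_equal(ca_rmsd_series(shifted)$rmsd_A[2], 0, tolerance = 1e-9)
})

test_that("isotropic Gaussian displacement gives rmsd near sigma * sqrt(3)", {
  n_ca <- 150; sigma <- 0.5
  base <- data.frame(serial = seq_len(n_ca), name = "CA", element = "C",
                     res_name = "ALA", res_seq = seq_len(n_ca), chain = "A",
                     x = rnorm(n_ca, sd = 8), y = rnorm(n_ca, sd = 8),
                     z = rnorm(n_ca, sd = 8), group = "peptide",
                     stringsAsFactors = FALSE)
  set.seed(74)
  frames <- c(list(mol_structure(base, 1)),
              lapply(2:21, function(k) {
                a <- base
                a$x <- a$x + rnorm(n_ca, sd = sigma)
                a$y <- a$y + rnorm(n_ca, sd = sigma)
                a$z <- a$z + rnorm(n_ca, sd = sigma)
                mol_structure(a, k)
              }))
  out <- ca_rmsd_series(frames)
  expect_equal(out$rmsd_A[1], 0, tolerance = 1e-12)
  expect_equal(mean(out$rmsd_A[-1]), sigma * sqrt(3), tolerance = 0.05)
})

test_that("hydrogen bonds require both the distance and the angle gate", {
  # ideal O-H...O: d(D-A) = 2.9 A, A-H-D angle 180 degrees
  ideal <- mol_structure(rbind(
    atom_row(1, "O", "O", 0, 0, 0, "peptide"),
    atom_row(2, "O1", "O", 2.9, 0, 0, "ligand"),
    atom_row(3, "H1", "H", 1.94, 0, 0, "ligand")))
  hb <- detect_hbonds(ideal)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance_A, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle_deg, 180, tolerance = 1e-9)

  # same geometry stretched to d = 3.6 fails the distance gate
  far <- mol_structure(rbind(
    atom_row(1, "O", "O", 0, 0, 0, "peptide"),
    atom_row(2, "O1", "O", 3.6, 0, 0, "ligand"),
    atom_row(3, "H1", "H", 2.64, 0, 0, "ligand")))
  expect_equal(nrow(detect_hbonds(far)), 0)

  # bent hydrogen (~124 degrees) fails the angle gate at d = 2.9
  psi <- 40 * pi / 180
  bent <- mol_structure(rbind(
    atom_row(1, "O", "O", 0, 0, 0, "peptide"),
    atom_row(2, "O1", "O", 2.9, 0, 0, "ligand"),
    atom_row(3, "H1", "H", 2.9 - 0.96 * cos(psi), 0.96 * sin(psi),
             0, "ligand")))
  expect_equal(nrow(detect_hbonds(bent)), 0)

  # boundary: exactly 3.5 A is excluded (strict inequality)
  edge <- mol_structure(rbind(
    atom_row(1, "O", "O", 0, 0, 0, "peptide"),
    atom_row(2, "O1", "O", 3.5, 0, 0, "ligand"),
    atom_row(3, "H1", "H", 2.54, 0, 0, "ligand")))
  expect_equal(nrow(detect_hbonds(edge)), 0)

  no_h <- mol_structure(rbind(
    atom_row(1, "O", "O", 0, 0, 0, "peptide"),
    atom_row(2, "O1", "O", 2.9, 0, 0, "ligand")))
  expect_error(detect_hbonds(no_h), "no hydrogens")
})

test_that("both donor directions are scanned and intramolecular pairs excluded", {
  # peptide is the donor here, ligand the acceptor
  pep_donor <- mol_structure(rbind(
    atom_row(1, "N", "N", 0, 0, 0, "peptide"),
    atom_row(2, "H", "H", 0.96, 0, 0, "peptide"),
    atom_row(3, "O1", "O", 2.9, 0, 0, "ligand")))
  hb <- detect_hbonds(pep_donor)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_idx, 1)
  expect_equal(hb$acceptor_idx, 3)

  # a perfect geometry entirely inside the peptide must not count
  intra <- mol_structure(rbind(
    atom_row(1, "N", "N", 0, 0, 0, "peptide"),
    atom_row(2, "H", "H", 0.96, 0, 0, "peptide"),
    atom_row(3, "O", "O", 2.9, 0, 0, "peptide", res_seq = 2L),
    atom_row(4, "C1", "C", 40, 40, 40, "ligand")))
  expect_equal(nrow(detect_hbonds(intra)), 0)
})

test_that("non-bonded contacts gate on element and the closed 2.9-3.9 window", {
  mk <- function(elem, d) mol_structure(rbind(
    atom_row(1, "CB", "C", 0, 0, 0, "peptide"),
    atom_row(2, paste0(elem, "1"), elem, d, 0, 0, "ligand")))
  expect_equal(count_nbc(mk("C", 3.0))$n, 1)
  expect_equal(count_nbc(mk("S", 3.5))$n, 1)
  expect_equal(count_nbc(mk("C", 2.5))$n, 0)   # below the window
  expect_equal(count_nbc(mk("C", 4.2))$n, 0)   # above the window
  expect_equal(count_nbc(mk("N", 3.0))$n, 0)   # not a hydrophobic atom
  expect_equal(count_nbc(mk("C", 2.9))$n, 1)   # closed lower endpoint
  expect_equal(count_nbc(mk("C", 3.9))$n, 1)   # closed upper endpoint

  # each qualifying pair counts once
  multi <- mol_structure(rbind(
    atom_row(1, "CB", "C", 0, 0, 0, "peptide"),
    atom_row(2, "CG", "C", 0, 3.2, 0, "peptide", res_seq = 2L),
    atom_row(3, "C1", "C", 3.0, 0, 0, "ligand"),
    atom_row(4, "C2", "C", 3.3, 3.2, 0, "ligand")))
  out <- count_nbc(multi)
  expect_equal(out$n, nrow(out$pairs))
  expect_gte(out$n, 2)
})

test_that("interface detectors are invariant under global rigid motion", {
  toy <- gen_toy_complex(12, 4, "hbond_ideal", seed = 44)
  s <- toy$structures[[1]]
  hb0 <- nrow(detect_hbonds(s))
  nbc0 <- count_nbc(s)$n
  expect_equal(hb0, 1)
  set.seed(45)
  for (i in 1:3) {
    R <- euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                        runif(1, 0, 2 * pi))
    shift <- runif(3, -30, 30)
    a <- s$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R) +
      matrix(rep(shift, each = nrow(a)), ncol = 3)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    moved <- mol_structure(a, 1)
    expect_equal(nrow(detect_hbonds(moved)), hb0)
    expect_equal(count_nbc(moved)$n, nbc0)
  }
})

test_that("hydrogen-bond counts average within then across replicas", {
  expect_equal(hbond_replica_average(list(c(0, 0), c(0, 0, 0))), 0)
  expect_equal(hbond_replica_average(list(c(1, 1), c(3, 3, 3))), 2)
  expect_error(hbond_replica_average(list()), "no replicas")
  expect_error(hbond_replica_average(list(numeric(0))), "at least one")

  set.seed(46)
  reps <- lapply(1:4, function(i) rpois(50, 2))
  expect_equal(hbond_replica_average(reps), mean(unlist(reps)),
               tolerance = 1e-12)
})
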