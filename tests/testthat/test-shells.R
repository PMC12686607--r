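# radial shell selection and the stability rule

test_that("shell membership matches a brute-force distance scan and is monotone", {
  s <- toy_fixture("shell", seed = 7, n_residues = 6)
  radii <- c(2, 4, 5, 6.5, 9, 15)
  prev <- character()
  for (r in radii) {
    sel <- select_shell(s, toy_ligand_id, r)
    expect_setequal(sel, brute_shell(s, toy_ligand_id, r))
    expect_true(all(prev %in% sel))  # nesting in r
    prev <- sel
  }
  # a radius covering everything returns all protein residues
  all_prot <- residue_table(s)$resid[residue_table(s)$role == "protein"]
  expect_setequal(select_shell(s, toy_ligand_id, 1e4), all_prot)
})

test_that("the shell boundary is closed (residue exactly at r is included)", {
  # hand-built two-residue system: one protein atom exactly 5 A from the
  # single ligand atom
  s <- mfccpocket:::as_structure_tbl(tibble::tibble(
    chain = c("A", "L"), resno = c(1L, 1L), inscode = "",
    resname = c("ALA", "LIG"), role = c("protein", "ligand"),
    atom = c("CA", "C1"), element = "C",
    x = c(0, 5), y = 0, z = 0, charge = 0
  ))
  expect_equal(select_shell(s, "L:1:", 5), "A:1:")
  expect_equal(length(select_shell(s, "L:1:", 4.999)), 0)
})

test_that("unknown ligand ids are lookup errors", {
  s <- toy_fixture("shell", seed = 7, n_residues = 6)
  expect_error(select_shell(s, "Z:9:", 5), class = "mfcc_lookup_error")
})

test_that("the stability rule reproduces the worked ratio example", {
  prof <- tibble::tibble(radius = c(1, 2, 3, 4, 5),
                         cumulative_energy = c(-10, -20, -25, -26, -26.5),
                         n_residues = 1:5)
  # steps: 0.5, 0.2, then |26-25|/26 = 0.038 < 0.10 -> converged at r = 3
  expect_equal(detect_convergence(prof, 0.10), 3)
})

test_that("stability rule edge cases: constant, diverging, short profiles", {
  const <- tibble::tibble(radius = c(0.5, 1, 1.5),
                          cumulative_energy = c(-5, -5, -5))
  expect_equal(detect_convergence(const, 0.10), 0.5)
  doubling <- tibble::tibble(radius = 1:6,
                             cumulative_energy = -2^(1:6))
  expect_true(is.na(detect_convergence(doubling, 0.10)))
  short <- tibble::tibble(radius = 1, cumulative_energy = -1)
  expect_error(detect_convergence(short), class = "mfcc_insufficient_data")
})

test_that("the stability rule is invariant to uniform energy rescaling", {
  p <- make_energy_profile(-30, 0.6, 12)
  r1 <- detect_convergence(p, 0.10)
  p2 <- p
  p2$cumulative_energy <- p2$cumulative_energy * 137.5
  expect_equal(detect_convergence(p2, 0.10), r1)
})

test_that("shell sweep accumulates energies on the half-Angstrom grid", {
  s <- toy_fixture("shell", seed = 7, n_residues = 6)
  dec <- decompose_pocket(s, r_max = 12)
  rec <- tidy(dec)
  prof <- dec$profile
  expect_equal(unique(diff(sort(unique(prof$radius)))), 0.5)
  # independent per-radius recomputation from the records
  dd <- mfccpocket:::residue_ligand_distances(s, toy_ligand_id)
  for (eps in c(10, 40)) {
    r_eps <- rec[rec$dielectric == eps, ]
    p_eps <- prof[prof$dielectric == eps, ]
    for (k in seq_len(nrow(p_eps))) {
      inside <- dd$resid[dd$min_distance <= p_eps$radius[k]]
      expect_equal(p_eps$cumulative_energy[k],
                   sum(r_eps$energy[r_eps$resid %in% inside]))
      expect_equal(p_eps$n_residues[k], length(inside))
    }
  }
  # counts are non-decreasing; energy constant where no residue enters
  for (eps in c(10, 40)) {
    p_eps <- prof[prof$dielectric == eps, ]
    expect_true(all(diff(p_eps$n_residues) >= 0))
    flat <- which(diff(p_eps$n_residues) == 0)
    expect_equal(p_eps$cumulative_energy[flat + 1],
                 p_eps$cumulative_energy[flat])
  }
})

test_that("a missing in-shell record is a completeness error", {
  s <- toy_fixture("shell", seed = 7, n_residues = 6)
  dec <- decompose_pocket(s, r_max = 12)
  rec <- tidy(dec)
  rec <- rec[rec$resid != rec$resid[1], ]
  expect_error(shell_sweep(rec, s, toy_ligand_id, 12),
               class = "mfcc_completeness_error")
})

test_that("single distant residue yields a step-function profile", {
  s <- mfccpocket:::as_structure_tbl(tibble::tibble(
    chain = c("A", "L"), resno = c(1L, 1L), inscode = "",
    resname = c("ALA", "LIG"), role = c("protein", "ligand"),
    atom = c("CA", "C1"), element = "C",
    x = c(1.2, 0), y = 0, z = 0, charge = 0
  ))
  rec <- tibble::tibble(resid = "A:1:", energy = -3.0, dielectric = 40)
  prof <- shell_sweep(rec, s, "L:1:", 3)
  expect_equal(prof$cumulative_energy, c(0, 0, -3, -3, -3, -3))
})
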