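# classical pair potential and the QM deck writer / log parser

two_atoms <- function(d, q1, q2) {
  mfccpocket:::as_structure_tbl(tibble::tibble(
    chain = "A", resno = c(1L, 2L), inscode = "", resname = "LIG",
    role = "ligand", atom = c("X1", "X2"), element = "C",
    x = c(0, d), y = 0, z = 0, charge = c(q1, q2)
  ))
}

test_that("the Coulomb term reproduces hand-evaluated pair energies", {
  # 332.0637 * (+1)(-1) / (1 * 3.320637) = -100 kcal/mol
  s <- two_atoms(3.320637, 1, -1)
  expect_equal(evaluate_classical(s, backend_classical(1, lj = FALSE)),
               -100, tolerance = 1e-10)
  # 1/eps scaling: same pair at eps = 40 -> -2.50
  expect_equal(evaluate_classical(s, backend_classical(40, lj = FALSE)),
               -2.5, tolerance = 1e-10)
})

test_that("degenerate systems and missing parameters are handled", {
  one <- two_atoms(1, 1, -1)[1, ]
  expect_equal(evaluate_classical(one, backend_classical(10)), 0)
  miss <- two_atoms(2, 1, -1)
  miss$charge[1] <- NA
  expect_error(evaluate_classical(miss, backend_classical(10)),
               class = "mfcc_parameterization_error")
  clash <- two_atoms(0.3, 0.1, 0.1)
  expect_warning(evaluate_classical(clash, backend_classical(10)), "clash")
})

test_that("the classical backend is exactly pairwise additive", {
  set.seed(404)
  for (rep in 1:5) {
    nA <- 4
    nB <- 5
    mk <- function(n, off) mfccpocket:::as_structure_tbl(tibble::tibble(
      chain = "A", resno = seq_len(n), inscode = "", resname = "LIG",
      role = "ligand", atom = paste0("X", seq_len(n)),
      element = sample(c("C", "N", "O", "H"), n, replace = TRUE),
      x = runif(n, 0, 5) + off, y = runif(n, 0, 5), z = runif(n, 0, 5),
      charge = runif(n, -0.5, 0.5)
    ))
    A <- mk(nA, 0)
    B <- mk(nB, 8)
    AB <- dplyr::bind_rows(A, B)
    spec <- backend_classical(10)
    # independent cross-term double loop
    cross <- 0
    for (i in seq_len(nA)) {
      for (j in seq_len(nB)) {
        d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                    (A$z[i] - B$z[j])^2)
        cross <- cross + 332.0637 * A$charge[i] * B$charge[j] / (10 * d)
        pa <- mfccpocket:::lj_params(A$element[i])
        pb <- mfccpocket:::lj_params(B$element[j])
        sg <- (pa$sigma + pb$sigma) / 2
        ep <- sqrt(pa$eps * pb$eps)
        cross <- cross + 4 * ep * ((sg / d)^12 - (sg / d)^6)
      }
    }
    expect_equal(evaluate_classical(AB, spec),
                 evaluate_classical(A, spec) + evaluate_classical(B, spec) +
                   cross,
                 tolerance = 1e-12)
  }
})

test_that("classical energies are invariant under rigid motion", {
  s <- toy_fixture("bk", seed = 19, n_residues = 5)
  sys <- build_fragment_systems(build_caps(s, "A:3:"), toy_ligand_id, s)$L_CRC
  spec <- backend_classical(10)
  e0 <- evaluate_classical(sys, spec)
  xyz <- as.matrix(sys[, c("x", "y", "z")])
  xyz <- mfccpocket:::rotate_about(xyz, c(1, 2, 3), 73.2)
  moved <- sys
  moved$x <- xyz[, 1] + 11.1
  moved$y <- xyz[, 2] - 5.4
  moved$z <- xyz[, 3] + 0.7
  expect_equal(evaluate_classical(moved, spec), e0, tolerance = 1e-9)
})

test_that("QM decks carry route, charge/multiplicity and dielectric", {
  water <- mfccpocket:::fragment_system(mfccpocket:::as_structure_tbl(
    tibble::tibble(
      chain = "W", resno = 1L, inscode = "", resname = "HOH",
      role = "water", atom = c("O", "H1", "H2"),
      element = c("O", "H", "H"),
      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0,
      charge = c(-0.834, 0.417, 0.417)
    )), term = "CRC")
  p <- withr::local_tempfile(fileext = ".gjf")
  write_qm_deck(water, backend_qm_deck(dielectric = 40), p)
  lines <- readLines(p)
  expect_match(lines[2], "B97D/6-311\\+G\\(d,p\\)")
  expect_match(lines[2], "SCRF=\\(CPCM")
  expect_equal(sum(lines == "0 1"), 1)
  expect_true(any(grepl("^eps=40$", lines)))
  coord <- grep("^[A-Z]\\s+-?\\d", lines)
  expect_equal(length(coord), 3)
})

test_that("deck writing enforces integer net charge and records anions", {
  s <- make_toy_complex(toy_spec(n_residues = 5,
                                 sequence = c("ALA", "ALA", "ASP", "ALA",
                                              "ALA"),
                                 seed = 18, n_waters = 0))
  sys <- build_fragment_systems(build_caps(s, "A:3:"), toy_ligand_id, s)
  p <- withr::local_tempfile(fileext = ".gjf")
  write_qm_deck(sys$CRC, backend_qm_deck(dielectric = 10), p)
  expect_true(any(readLines(p) == "-1 1"))
  bad <- sys$CRC
  attr(bad, "net_charge") <- NA_integer_
  expect_error(write_qm_deck(bad, backend_qm_deck(), p),
               class = "mfcc_spec_error")
})

test_that("log parsing converts the last SCF energy to kcal/mol", {
  expect_equal(parse_qm_energy("SCF Done:  E(RB97D) = -1.000000  A.U."),
               -627.509474, tolerance = 1e-9)
  two <- c("SCF Done:  E(RB97D) = -2.000000  A.U.",
           "SCF Done:  E(RB97D) = -1.500000  A.U.")
  expect_equal(as.numeric(parse_qm_energy(two)), -1.5 * 627.509474)
  # D-exponent notation
  expect_equal(as.numeric(parse_qm_energy("SCF Done: E = -0.1D+01 after")),
               -627.509474, tolerance = 1e-9)
  expect_error(parse_qm_energy("no energies here"),
               class = "mfcc_parse_error")
  expect_error(parse_qm_energy(c("SCF Done: E = -1.0",
                                 ">>>> Convergence failure")),
               class = "mfcc_convergence_error")
})
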