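# conjugated-cap construction, water attachment, fragment assembly

test_that("a middle residue gets two whole-residue caps and two saturation hydrogens", {
  s <- toy_fixture("frag", seed = 13, n_residues = 5, n_waters = 0)
  capped <- build_caps(s, "A:3:")
  expect_equal(capped$cap_prev$resid[1], "A:2:")
  expect_equal(capped$cap_next$resid[1], "A:4:")
  expect_equal(nrow(capped$cap_hydrogens), 2)
  # caps are entire residues, side chains included
  expect_setequal(capped$cap_prev$atom,
                  s$atom[s$resid == "A:2:"])
})

test_that("terminal residues get single-sided caps with real end groups", {
  s <- toy_fixture("frag", seed = 13, n_residues = 5, n_waters = 0)
  capped <- build_caps(s, "A:1:")
  expect_null(capped$cap_prev)
  expect_equal(capped$cap_next$resid[1], "A:2:")
  expect_equal(nrow(capped$cap_hydrogens), 1)
  # the N-cap of residue 2 retains the real zwitterionic terminus of 1
  expect_true(all(c("H1", "H2", "H3") %in% capped$residue$atom))
})

test_that("saturation hydrogens lie on the former bond at standard lengths", {
  s <- toy_fixture("frag", seed = 13, n_residues = 5, n_waters = 0)
  capped <- build_caps(s, "A:3:")
  ch <- capped$cap_hydrogens
  # N-side: H replaces C(i-2) at 1.01 A from N(i-1)
  n_pos <- as.numeric(s[s$resid == "A:2:" & s$atom == "N", c("x", "y", "z")])
  c_pos <- as.numeric(s[s$resid == "A:1:" & s$atom == "C", c("x", "y", "z")])
  h_pos <- as.numeric(ch[grepl("^N", ch$saturates), c("x", "y", "z")])
  expect_equal(sqrt(sum((h_pos - n_pos)^2)), 1.01, tolerance = 1e-3)
  # collinear with the former bond: distance from the N->C segment ~ 0
  u <- (c_pos - n_pos) / sqrt(sum((c_pos - n_pos)^2))
  proj <- n_pos + sum((h_pos - n_pos) * u) * u
  expect_lt(sqrt(sum((h_pos - proj)^2)), 1e-3)
  # C-side at 1.09 A
  c2 <- as.numeric(s[s$resid == "A:4:" & s$atom == "C", c("x", "y", "z")])
  h2 <- as.numeric(ch[grepl("^C", ch$saturates), c("x", "y", "z")])
  expect_equal(sqrt(sum((h2 - c2)^2)), 1.09, tolerance = 1e-3)
})

test_that("chain discontinuities are rejected", {
  s <- toy_fixture("frag", seed = 13, n_residues = 5, n_waters = 0)
  shifted <- s
  move <- shifted$resid %in% c("A:4:", "A:5:")
  shifted$x[move] <- shifted$x[move] + 4
  expect_error(build_caps(shifted, "A:3:"),
               class = "mfcc_chain_discontinuity")
})

test_that("waters attach to the nearest hydrogen-bonded residue", {
  # crafted case: water oxygen 2.8 A from residue A's carbonyl O and
  # 3.2 A from residue B's N -> assigned to A
  s <- mfccpocket:::as_structure_tbl(tibble::tibble(
    chain = c("A", "A", "W"), resno = c(1L, 2L, 1L), inscode = "",
    resname = c("ALA", "ALA", "HOH"),
    role = c("protein", "protein", "water"),
    atom = c("O", "N", "O"), element = c("O", "N", "O"),
    x = c(0, 6, 2.8), y = 0, z = 0, charge = 0
  ))
  m <- assign_waters(s, c("A:1:", "A:2:"), 3.5)
  expect_equal(m$residue, "A:1:")
  expect_equal(m$distance, 2.8)
  # beyond the cutoff: unassigned
  far <- s
  far$x[far$role == "water"] <- 4.2
  expect_true(is.na(assign_waters(far, c("A:1:"), 3.5)$residue))
})

test_that("water assignment matches exhaustive nearest-qualifying search", {
  for (sd in c(3, 14, 15)) {
    s <- make_toy_complex(toy_spec(seed = sd, n_residues = 7, n_waters = 3,
                                   water_residues = c(2, 4, 6)))
    pocket <- residue_table(s)$resid[residue_table(s)$role == "protein"]
    m <- assign_waters(s, pocket, 3.5)
    brute <- brute_water_assign(s, pocket, 3.5)
    for (i in seq_len(nrow(m))) {
      expect_identical(m$residue[i], brute[[m$water[i]]])
    }
    # no water is attached to two residues
    expect_false(any(duplicated(m$water)))
  }
})

test_that("fragment systems respect the four-term structure and charges", {
  sq <- c("ALA", "ALA", "ASP", "ALA", "ALA")
  s <- make_toy_complex(toy_spec(n_residues = 5, sequence = sq, seed = 17,
                                 n_waters = 1, water_residues = 3))
  m <- assign_waters(s, "A:3:", 3.5)
  w <- m$water[!is.na(m$residue)]
  capped <- build_caps(s, "A:3:", waters = w)
  sys <- build_fragment_systems(capped, toy_ligand_id, s)
  expect_named(sys, c("L_CRC", "L_CC", "CRC", "CC"))

  # charge bookkeeping: R_i = ASP (-1), neutral ligand
  expect_equal(attr(sys$L_CRC, "net_charge"), -1L)
  expect_equal(attr(sys$CRC, "net_charge"), -1L)
  expect_equal(attr(sys$L_CC, "net_charge"), 0L)
  expect_equal(attr(sys$CC, "net_charge"), 0L)

  # atom-count identity: |L_CRC| - |L_CC| = |CRC| - |CC|
  expect_equal(nrow(sys$L_CRC) - nrow(sys$L_CC),
               nrow(sys$CRC) - nrow(sys$CC))

  # no ligand atoms in CRC/CC; no duplicated atoms within a term
  for (term in c("CRC", "CC")) {
    expect_false(any(sys[[term]]$role == "ligand"))
  }
  for (term in names(sys)) {
    df <- sys[[term]]
    expect_false(any(duplicated(df[!df$sat_h, c("resid", "atom")])))
  }

  # attached waters travel with the residue: in L_CRC/CRC, not L_CC/CC
  expect_true(any(sys$L_CRC$role == "water"))
  expect_true(any(sys$CRC$role == "water"))
  expect_false(any(sys$L_CC$role == "water"))
  expect_false(any(sys$CC$role == "water"))
})

test_that("saturation hydrogens are uncharged placeholders", {
  s <- toy_fixture("frag", seed = 13, n_residues = 5, n_waters = 0)
  sys <- build_fragment_systems(build_caps(s, "A:3:"), toy_ligand_id, s)
  sat <- sys$CC[sys$CC$sat_h, ]
  expect_gt(nrow(sat), 0)
  expect_true(all(sat$charge == 0))
})
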