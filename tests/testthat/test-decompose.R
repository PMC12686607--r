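# four-term combination, pocket decomposition, ranking, annotation

test_that("the four-term combination cancels caps exactly for additive backends", {
  for (sd in c(2, 9, 27)) {
    s <- make_toy_complex(toy_spec(seed = sd, n_residues = 6, n_waters = 2))
    dec <- decompose_pocket(s, r_max = 15)
    rec <- tidy(dec)
    for (i in seq_len(nrow(rec))) {
      o <- oracle_pairwise(s, dec$ligand_id, rec$resid[i],
                           rec$dielectric[i], waters = rec$waters[[i]])
      expect_lt(abs(rec$energy[i] - o), 1e-8)
    }
  }
})

test_that("equal term energies combine to zero", {
  expect_equal(combine_mfcc_terms(12.3, 12.3, 12.3, 12.3), 0)
  expect_equal(combine_mfcc_terms(-5, 2, -5, 2), 0)
})

test_that("a far-displaced ligand contributes nothing", {
  s <- make_toy_complex(toy_spec(seed = 8, n_residues = 5, n_waters = 0,
                                 ligand_distance = 100))
  capped <- build_caps(s, "A:3:")
  sys <- build_fragment_systems(capped, toy_ligand_id, s)
  expect_lt(abs(mfcc_energy(sys, backend_classical())), 1e-3)
})

test_that("per-residue records sum to the whole-pocket pairwise energy", {
  s <- make_toy_complex(toy_spec(seed = 12, n_residues = 6, n_waters = 0))
  dec <- decompose_pocket(s, r_max = 40)
  rec <- tidy(dec)
  prot <- residue_table(s)
  prot <- prot$resid[prot$role == "protein"]
  for (eps in c(10, 40)) {
    total <- sum(vapply(prot, function(id) {
      oracle_pairwise(s, dec$ligand_id, id, eps, include_waters = FALSE)
    }, numeric(1)))
    expect_equal(sum(rec$energy[rec$dielectric == eps]), total,
                 tolerance = 1e-9)
  }
})

test_that("decomposition is invariant under rigid motion of the complex", {
  s <- make_toy_complex(toy_spec(seed = 33, n_residues = 5))
  dec1 <- tidy(decompose_pocket(s, r_max = 12))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  xyz <- mfccpocket:::rotate_about(xyz, c(0, 1, 1), 41)
  s2 <- s
  s2$x <- xyz[, 1] - 3
  s2$y <- xyz[, 2] + 7
  s2$z <- xyz[, 3] + 2
  dec2 <- tidy(decompose_pocket(s2, r_max = 12))
  expect_equal(dec2$energy, dec1$energy, tolerance = 1e-8)
})

test_that("higher dielectric screens the Coulomb interaction", {
  s <- make_toy_complex(toy_spec(seed = 6, n_residues = 6, n_waters = 0))
  dec <- decompose_pocket(s, r_max = 15, backend = backend_classical(lj = FALSE))
  rec <- tidy(dec) |>
    tidyr::pivot_wider(id_cols = "resid", names_from = "dielectric",
                       values_from = "energy", names_prefix = "eps")
  expect_true(all(abs(rec$eps40) <= abs(rec$eps10) + 1e-12))
  # Coulomb-only energies scale exactly as 1/eps
  expect_equal(rec$eps40, rec$eps10 * 10 / 40, tolerance = 1e-12)
})

test_that("ranking orders attractive then repulsive residues", {
  rec <- tibble::tibble(
    resid = c("A:63:", "A:62:", "A:70:"),
    resname = c("ASP", "PRO", "VAL"), chain = "A",
    resno = c(63L, 62L, 70L),
    energy = c(-4.17, 2.28, -1.62), dielectric = 40
  )
  rk <- rank_residues(rec)
  expect_equal(rk$energy, c(-4.17, -1.62, 2.28))
  expect_equal(rk$classification, c("attractive", "attractive", "repulsive"))
  # all-zero energies keep input order
  z <- rec
  z$energy <- 0
  expect_equal(rank_residues(z)$resid, rec$resid)
  one <- rank_residues(rec[1, ])
  expect_equal(one$resid, "A:63:")
})

test_that("contact annotation finds the nearest ligand atom and region", {
  s <- toy_fixture("dc", seed = 3)
  regions <- toy_ligand_regions()
  dec <- decompose_pocket(s, r_max = 12, region_map = regions)
  rec <- tidy(dec)
  expect_true(all(rec$contact_region %in% c("i", "ii", "iii")))
  # brute-force nearest-atom check for one residue
  id <- rec$resid[1]
  res <- s[s$resid == id, ]
  lig <- s[s$resid == dec$ligand_id, ]
  best <- Inf
  best_atom <- NA
  for (j in seq_len(nrow(lig))) {
    for (i in seq_len(nrow(res))) {
      d <- sqrt((res$x[i] - lig$x[j])^2 + (res$y[i] - lig$y[j])^2 +
                  (res$z[i] - lig$z[j])^2)
      if (d < best) {
        best <- d
        best_atom <- lig$atom[j]
      }
    }
  }
  expect_equal(rec$nearest_ligand_atom[rec$resid == id][1], best_atom)
  expect_equal(rec$min_distance[rec$resid == id][1], best, tolerance = 1e-9)
})

test_that("region map gaps are annotation errors", {
  s <- toy_fixture("dc", seed = 3)
  partial <- toy_ligand_regions()[1:3, ]
  rec <- tibble::tibble(resid = "A:4:")
  expect_error(annotate_contact(rec, s, toy_ligand_id, partial),
               class = "mfcc_annotation_error")
})

test_that("tidy/glance/autoplot expose the decomposition", {
  s <- toy_fixture("dc", seed = 3)
  dec <- decompose_pocket(s, r_max = 12)
  g <- glance(dec)
  expect_equal(g$dielectric, c(10, 40))
  expect_equal(g$total_energy,
               tapply(tidy(dec)$energy, tidy(dec)$dielectric, sum),
               ignore_attr = TRUE)
  expect_s3_class(autoplot(dec), "ggplot")
  expect_s3_class(autoplot(dec$profile), "ggplot")
})
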