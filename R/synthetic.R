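# Seeded desk-scale complex generator and brute-force oracles. The peptide
# is built in an idealized extended conformation (phi = psi = omega = 180)
# with template side chains; the ligand is a rigid 12-atom quinone-like
# molecule that is inversion-symmetric (net charge zero, zero dipole), so
# long-range interactions with any residue fall off at least as fast as
# charge-quadrupole terms. Waters are placed at hydrogen-bond range of
# chosen carbonyl oxygens.

# side-chain heavy-atom z-matrices: new atom, (a, b, c) frame, bond,
# angle (new-c-b), torsion (new-c-b-a)
.SC_ZMAT <- list(
  ALA = list(),
  SER = list(c("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.43, 109.6, 60),
             c("CG2", "N", "CA", "CB", 1.52, 110.5, 180)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.52, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.52, 110.5, -60)),
  ASP = list(c("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.25, 118.4, 0),
             c("OD2", "CA", "CB", "CG", 1.25, 118.4, 180)),
  GLU = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.25, 118.4, 0),
             c("OE2", "CB", "CG", "CD", 1.25, 118.4, 180)),
  LYS = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             c("CE", "CB", "CG", "CD", 1.52, 111.3, 180),
             c("NZ", "CG", "CD", "CE", 1.49, 110.5, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             c("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.33, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("SD", "CA", "CB", "CG", 1.80, 112.7, 180),
             c("CE", "CB", "CG", "SD", 1.79, 100.9, 180)),
  PHE = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.39, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.39, 120.8, -90),
             c("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  HIS = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.38, 122.7, 90),
             c("CD2", "CA", "CB", "CG", 1.36, 131.1, -90),
             c("CE1", "CB", "CG", "ND1", 1.32, 109.3, 180),
             c("NE2", "CB", "CG", "CD2", 1.37, 107.2, 180)),
  GLY = list()
)

builder_residues <- function() sort(c(names(.SC_ZMAT)))

# the rigid quinone-like toy ligand: inversion symmetric, net charge 0
toy_ligand_template <- function() {
  rad <- 1.39
  hex <- map(0:5, function(k) {
    th <- k * pi / 3
    rad * c(cos(th), sin(th), 0)
  })
  hr <- rad + 1.09
  tibble(
    atom = c("C1", "C2", "C3", "C4", "C5", "C6", "O7", "O8",
             "H2", "H3", "H5", "H6"),
    element = c(rep("C", 6), "O", "O", rep("H", 4)),
    x = c(map_dbl(hex, 1), 2.62, -2.62,
          hr * cos(pi / 3), hr * cos(2 * pi / 3),
          hr * cos(4 * pi / 3), hr * cos(5 * pi / 3)),
    y = c(map_dbl(hex, 2), 0, 0,
          hr * sin(pi / 3), hr * sin(2 * pi / 3),
          hr * sin(4 * pi / 3), hr * sin(5 * pi / 3)),
    z = 0,
    charge = c(0.45, -0.115, -0.115, 0.45, -0.115, -0.115,
               -0.45, -0.45, 0.115, 0.115, 0.115, 0.115)
  )
}

#' Region map of the toy ligand
#'
#' Three labeled regions over the toy ligand's heavy atoms, mirroring the
#' region subdivision used when reporting which part of a ligand each
#' pocket residue contacts.
#'
#' @return tibble with columns `atom`, `region`.
#' @export
toy_ligand_regions <- function() {
  tibble(
    atom = c("C1", "O7", "C2", "C3", "C5", "C6", "C4", "O8"),
    region = c("i", "i", "ii", "ii", "ii", "ii", "iii", "iii")
  )
}

#' Specification for a synthetic toy complex
#'
#' @param n_residues peptide length (>= 3 so at least one residue has both
#'   caps).
#' @param sequence character vector of three-letter codes (length
#'   `n_residues`); defaults to poly-ALA with an ASP near the N-terminus
#'   and a LYS near the C-terminus. Supported residues:
#'   ALA, ARG, ASP, GLU, GLY, HIS, LYS, MET, PHE, SER, THR, VAL.
#' @param ligand_distance distance in A from the anchor residue (middle of
#'   the chain) CA to the ligand centroid.
#' @param n_waters number of waters placed at hydrogen-bond range
#'   (2.7-3.3 A) of distinct backbone carbonyl oxygens.
#' @param seed integer seed; fully determines the output.
#' @param jitter standard deviation (A) of Gaussian positional noise added
#'   to the heavy atoms.
#' @param ligand_charge_scale multiplies the ligand template charges.
#' @param termini terminus chemistry passed to [assign_protonation()].
#' @param water_residues optional indices of the residues to hydrate.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(n_residues = 7, sequence = NULL, ligand_distance = 6,
                     n_waters = 2, seed = 1, jitter = 0.05,
                     ligand_charge_scale = 1,
                     termini = "zwitterionic", water_residues = NULL) {
  if (n_residues < 3) abort("n_residues must be at least 3")
  if (is.null(sequence)) {
    sequence <- rep("ALA", n_residues)
    sequence[2] <- "ASP"
    if (n_residues >= 5) sequence[n_residues - 1] <- "LYS"
  }
  if (length(sequence) != n_residues) {
    abort("sequence length must equal n_residues")
  }
  bad <- setdiff(sequence, builder_residues())
  if (length(bad) > 0) {
    abort(paste0("no builder template for residue(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  structure(list(n_residues = n_residues, sequence = sequence,
                 ligand_distance = ligand_distance, n_waters = n_waters,
                 seed = as.integer(seed), jitter = jitter,
                 ligand_charge_scale = ligand_charge_scale,
                 termini = termini, water_residues = water_residues),
            class = "toy_spec")
}

build_extended_peptide <- function(sequence) {
  n <- length(sequence)
  rows <- list()
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- place_atom(c(0, 1, 0), N, CA, 1.525, 111.2, 0)
    } else {
      N <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, 180)
      CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, 180)
      C <- place_atom(prevC, N, CA, 1.525, 111.2, 180)
    }
    O <- place_atom(N, CA, C, 1.231, 120.5, 0)
    pos <- list(N = N, CA = CA, C = C, O = O)
    if (sequence[i] != "GLY") {
      pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.53, 110.5, 122.5)
    }
    for (zm in .SC_ZMAT[[sequence[i]]]) {
      pos[[zm[1]]] <- place_atom(pos[[zm[2]]], pos[[zm[3]]], pos[[zm[4]]],
                                 as.numeric(zm[5]), as.numeric(zm[6]),
                                 as.numeric(zm[7]))
    }
    xyz <- do.call(rbind, pos)
    rows[[i]] <- tibble(
      chain = "A", resno = i, inscode = "", resname = sequence[i],
      role = "protein", atom = names(pos),
      element = element_of(names(pos)),
      x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3])
    )
    prevN <- N; prevCA <- CA; prevC <- C
  }
  bind_rows(rows)
}

#' Generate a seeded synthetic protein-ligand complex
#'
#' Builds an extended-conformation peptide with idealized geometry and
#' template side chains, places the rigid toy ligand at
#' `ligand_distance` from the middle residue in a random orientation, adds
#' waters at hydrogen-bond range of selected backbone carbonyls, applies
#' Gaussian positional jitter, and finishes with [assign_protonation()] so
#' the result is hydrogen-complete with charges. Fully reproducible from
#' the seed.
#'
#' @param spec a [toy_spec()].
#' @return atom tibble; the generating spec is recorded in the `source`
#'   attribute.
#' @export
make_toy_complex <- function(spec = toy_spec()) {
  if (!inherits(spec, "toy_spec")) abort("spec must be a toy_spec")
  withr::with_seed(spec$seed, {
    pep <- build_extended_peptide(spec$sequence)
    anchor <- ceiling(spec$n_residues / 2)
    ca <- pep |> filter(.data$resno == anchor, .data$atom == "CA")
    ca_pos <- as.numeric(ca[1, c("x", "y", "z")])

    lig_t <- toy_ligand_template()
    lig_xyz <- as.matrix(lig_t[, c("x", "y", "z")])
    axis <- rnorm(3)
    lig_xyz <- rotate_about(lig_xyz, axis, runif(1, 0, 360))

    pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
    # approach direction perpendicular to the chain axis (x), so no residue
    # along the extended chain ends up closer to the ligand than the anchor
    placed <- FALSE
    for (try in 1:25) {
      th <- deg2rad(runif(1, 0, 360))
      dir <- c(0, cos(th), sin(th))
      centroid <- ca_pos + spec$ligand_distance * dir
      cand <- sweep(lig_xyz, 2, centroid, "+")
      d2 <- outer(rowSums(cand^2), rep(1, nrow(pep_xyz))) +
        outer(rep(1, nrow(cand)), rowSums(pep_xyz^2)) -
        2 * cand %*% t(pep_xyz)
      dmin <- sqrt(max(min(d2), 0))
      if (dmin >= 2.5 || spec$ligand_distance > 20) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("could not place the ligand without steric clash",
            class = "mfcc_generation_error")
    }
    lig <- tibble(
      chain = "L", resno = 1L, inscode = "", resname = "LIG",
      role = "ligand", atom = lig_t$atom, element = lig_t$element,
      x = cand[, 1], y = cand[, 2], z = cand[, 3],
      charge = lig_t$charge * spec$ligand_charge_scale
    )

    # jitter perturbs the peptide only: the ligand is placed as a rigid
    # body (random orientation already randomises it between seeds)
    if (spec$jitter > 0) {
      pep$x <- pep$x + rnorm(nrow(pep), sd = spec$jitter)
      pep$y <- pep$y + rnorm(nrow(pep), sd = spec$jitter)
      pep$z <- pep$z + rnorm(nrow(pep), sd = spec$jitter)
    }
    heavy <- bind_rows(pep, lig)

    # waters at hydrogen-bond range of distinct backbone carbonyl oxygens
    wat <- NULL
    if (spec$n_waters > 0) {
      targets <- spec$water_residues %||%
        unique(round(seq(2, max(2, spec$n_residues - 1),
                         length.out = spec$n_waters)))
      targets <- head(targets, spec$n_waters)
      wrows <- list()
      occupied <- as.matrix(heavy[, c("x", "y", "z")])
      for (k in seq_along(targets)) {
        res_i <- targets[k]
        sel_o <- heavy$role == "protein" & heavy$resno == res_i &
          heavy$atom == "O"
        o <- heavy[sel_o, ]
        cc <- heavy[heavy$role == "protein" & heavy$resno == res_i &
                      heavy$atom == "C", ]
        opos <- as.numeric(o[1, c("x", "y", "z")])
        cpos <- as.numeric(cc[1, c("x", "y", "z")])
        d <- runif(1, 2.7, 3.3)
        # scan tilted directions around the carbonyl axis and keep the
        # first placement clear of every other atom
        u0 <- unitv(opos - cpos)
        p1 <- unitv(vcross(u0, if (abs(u0[1]) < 0.9) c(1, 0, 0)
                           else c(0, 1, 0)))
        p2 <- vcross(u0, p1)
        keep <- setdiff(seq_len(nrow(occupied)), which(sel_o))
        others <- occupied[keep, , drop = FALSE]
        wpos <- NULL
        for (tilt in seq(0, 60, by = 15)) {
          for (az in seq(0, 330, by = 30)) {
            dirc <- cos(deg2rad(tilt)) * u0 +
              sin(deg2rad(tilt)) * (cos(deg2rad(az)) * p1 +
                                      sin(deg2rad(az)) * p2)
            cand_w <- opos + d * dirc
            clear <- sqrt(rowSums(sweep(others, 2, cand_w)^2))
            if (min(clear) >= 2.4) {
              wpos <- cand_w
              break
            }
          }
          if (!is.null(wpos)) break
        }
        if (is.null(wpos)) {
          abort(paste0("could not place a water near residue ", res_i,
                       " without steric clash"),
                class = "mfcc_generation_error")
        }
        occupied <- rbind(occupied, wpos)
        wrows[[k]] <- tibble(
          chain = "W", resno = 1000L + k, inscode = "", resname = "HOH",
          role = "water", atom = "O", element = "O",
          x = wpos[1], y = wpos[2], z = wpos[3], charge = NA_real_
        )
      }
      wat <- bind_rows(wrows)
    }

    all_heavy <- as_structure_tbl(bind_rows(heavy, wat))
    d <- dist(as.matrix(all_heavy[, c("x", "y", "z")]))
    if (min(d) < 0.8) {
      abort("generated structure contains an unavoidable clash",
            class = "mfcc_generation_error")
    }
    out <- assign_protonation(all_heavy, termini = spec$termini)
    attr(out, "title") <- sprintf("synthetic toy complex (seed %d)",
                                  spec$seed)
    attr(out, "source") <- list(kind = "synthetic", seed = spec$seed,
                                spec = unclass(spec))
    out
  })
}

#' Brute-force pairwise ligand-residue interaction energy
#'
#' Independent supermolecule oracle: a direct double sum of the screened
#' Coulomb (+ optional Lennard-Jones) pair potential over every
#' ligand-atom / residue-atom pair, with attached waters pooled into the
#' residue side when requested. Shares only the pair-potential formula with
#' the fragment pipeline -- no caps, no fragment systems.
#'
#' @param structure atom tibble with charges.
#' @param ligand_id ligand residue id.
#' @param residue_id residue id.
#' @param dielectric uniform dielectric.
#' @param include_waters pool the waters listed in `waters` with the
#'   residue.
#' @param waters water residue ids attached to this residue.
#' @param lj include the Lennard-Jones term.
#' @return interaction energy in kcal/mol.
#' @export
oracle_pairwise <- function(structure, ligand_id, residue_id, dielectric,
                            include_waters = TRUE, waters = character(),
                            lj = TRUE) {
  lig <- structure[structure$resid == ligand_id, ]
  ids <- residue_id
  if (include_waters && length(waters) > 0) ids <- c(ids, waters)
  res <- structure[structure$resid %in% ids, ]
  if (nrow(lig) == 0 || nrow(res) == 0) abort("empty ligand or residue")
  if (anyNA(lig$charge) || anyNA(res$charge)) {
    abort("all atoms need partial charges",
          class = "mfcc_parameterization_error")
  }
  e <- 0
  for (i in seq_len(nrow(lig))) {
    pl <- lj_params(lig$element[i])
    for (j in seq_len(nrow(res))) {
      d <- sqrt((lig$x[i] - res$x[j])^2 + (lig$y[i] - res$y[j])^2 +
                  (lig$z[i] - res$z[j])^2)
      e <- e + .KCOUL * lig$charge[i] * res$charge[j] / (dielectric * d)
      if (lj) {
        pr <- lj_params(res$element[j])
        sg <- (pl$sigma + pr$sigma) / 2
        ep <- sqrt(pl$eps * pr$eps)
        sr6 <- (sg / d)^6
        e <- e + 4 * ep * (sr6^2 - sr6)
      }
    }
  }
  unname(e)
}

#' Synthetic cumulative energy profile with known convergence point
#'
#' Builds a shell profile whose totals approach `plateau` geometrically:
#' `E_k = plateau (1 - rate^k)`, optionally with Gaussian noise. For the
#' noiseless profile the stability rule has the closed form ratio
#' `rate^k (1 - rate) / (1 - rate^(k+1))`, from which the ground-truth
#' convergence radius is computed independently of [detect_convergence()]
#' and stored in attribute `ground_truth_radius`.
#'
#' @param plateau limiting total energy in kcal/mol.
#' @param approach_rate geometric rate in (0, 1); larger = slower approach.
#' @param n_points number of grid points (>= 3).
#' @param noise_sd Gaussian noise on each total, kcal/mol.
#' @param seed RNG seed for the noise.
#' @param threshold stability threshold used for the ground truth.
#' @return a `shell_profile` tibble with attribute `ground_truth_radius`.
#' @export
make_energy_profile <- function(plateau, approach_rate, n_points,
                                noise_sd = 0, seed = 1, threshold = 0.10) {
  if (n_points < 3) abort("n_points must be at least 3")
  if (approach_rate <= 0 || approach_rate >= 1) {
    abort("approach_rate must be in (0, 1)")
  }
  radii <- seq(0.5, by = 0.5, length.out = n_points)
  k <- seq_len(n_points)
  e <- plateau * (1 - approach_rate^k)
  if (noise_sd > 0) {
    e <- e + withr::with_seed(seed, rnorm(n_points, sd = noise_sd))
  }
  gt <- NA_real_
  if (plateau != 0) {
    for (kk in seq_len(n_points - 1)) {
      ratio <- approach_rate^kk * (1 - approach_rate) /
        (1 - approach_rate^(kk + 1))
      if (ratio < threshold) {
        gt <- radii[kk]
        break
      }
    }
  }
  prof <- new_shell_profile(
    tibble(radius = radii, n_residues = k, cumulative_energy = e),
    threshold
  )
  attr(prof, "ground_truth_radius") <- gt
  prof
}
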