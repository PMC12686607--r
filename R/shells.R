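# Radial-shell selection of binding-pocket residues on the r = n/2 grid,
# cumulative total binding energy per shell, and the <10% stability
# criterion for the converged pocket radius.

# minimum distance of every residue to any ligand atom
residue_ligand_distances <- function(structure, ligand_id,
                                     atom_mode = "all_atoms",
                                     include_waters = FALSE) {
  lig <- res_atoms(structure, ligand_id)
  if (nrow(lig) == 0) {
    abort(paste0("ligand not found: ", ligand_id), class = "mfcc_lookup_error")
  }
  if (lig$role[1] != "ligand") {
    abort(paste0(ligand_id, " does not have role=ligand"),
          class = "mfcc_lookup_error")
  }
  roles <- if (include_waters) c("protein", "water") else "protein"
  cand <- structure |> filter(.data$role %in% roles)
  if (atom_mode == "heavy_atoms") {
    cand <- cand |> filter(.data$element != "H")
    lig <- lig |> filter(.data$element != "H")
  }
  lx <- as.matrix(lig[, c("x", "y", "z")])
  cx <- as.matrix(cand[, c("x", "y", "z")])
  # min over ligand atoms for every candidate atom
  d2 <- outer(rowSums(cx^2), rep(1, nrow(lx))) +
    outer(rep(1, nrow(cx)), rowSums(lx^2)) - 2 * cx %*% t(lx)
  dmin_atom <- sqrt(pmax(apply(d2, 1, min), 0))
  tibble(resid = cand$resid, d = dmin_atom) |>
    group_by(.data$resid) |>
    summarise(min_distance = min(.data$d), .groups = "drop") |>
    arrange(match(.data$resid, unique(structure$resid)))
}

#' Select pocket residues within a radius of the ligand
#'
#' Returns every protein residue (and, optionally, water) having at least
#' one atom within Euclidean distance `r` of any ligand atom. The boundary
#' is closed (`<= r`), so membership is monotone in `r`.
#'
#' @param structure atom tibble.
#' @param ligand_id ligand residue id.
#' @param r shell radius in A (> 0).
#' @param atom_mode `"all_atoms"` (default; hydrogens count) or
#'   `"heavy_atoms"`.
#' @param include_waters also return water residues inside the shell.
#' @return character vector of residue ids, in structure order.
#' @export
select_shell <- function(structure, ligand_id, r,
                         atom_mode = c("all_atoms", "heavy_atoms"),
                         include_waters = FALSE) {
  atom_mode <- match.arg(atom_mode)
  if (r <= 0) abort("shell radius must be positive")
  dd <- residue_ligand_distances(structure, ligand_id, atom_mode,
                                 include_waters)
  dd$resid[dd$min_distance <= r]
}

new_shell_profile <- function(df, threshold) {
  structure(as_tibble(df),
            class = c("shell_profile", class(tibble())),
            threshold = threshold,
            convention = "relative change |E_{k+1} - E_k| / |E_{k+1}|")
}

#' Cumulative binding energy over the r = n/2 shell grid
#'
#' For each radius on the grid 0.5, 1.0, ..., `r_max`, sums the per-residue
#' interaction energies of all residues inside the shell and counts them.
#' Every residue within `r_max` must carry an energy record.
#'
#' @param records per-residue energy table with columns `resid`, `energy`
#'   and (optionally) `dielectric`; typically `tidy()` of a decomposition.
#' @param structure atom tibble.
#' @param ligand_id ligand residue id.
#' @param r_max outer radius in A (>= 0.5).
#' @param atom_mode distance criterion passed to [select_shell()].
#' @param threshold stability threshold stored with the profile.
#' @return a `shell_profile`: tibble with columns `dielectric`, `radius`,
#'   `n_residues`, `cumulative_energy`.
#' @export
shell_sweep <- function(records, structure, ligand_id, r_max = 10,
                        atom_mode = "all_atoms", threshold = 0.10) {
  if (r_max < 0.5) abort("r_max must be at least 0.5 A")
  grid <- seq(0.5, r_max, by = 0.5)
  dd <- residue_ligand_distances(structure, ligand_id, atom_mode)
  if (!"dielectric" %in% names(records)) records$dielectric <- NA_real_
  records <- records[, c("resid", "energy", "dielectric")]

  in_range <- dd$resid[dd$min_distance <= r_max]
  missing <- setdiff(in_range, unique(records$resid))
  if (length(missing) > 0) {
    abort(paste0("no energy record for in-shell residue(s): ",
                 paste(missing, collapse = ", ")),
          class = "mfcc_completeness_error")
  }
  rec <- records |> left_join(dd, by = "resid")
  prof <- rec |>
    group_by(.data$dielectric) |>
    group_modify(function(d, key) {
      tibble(
        radius = grid,
        n_residues = vapply(grid, function(r) sum(d$min_distance <= r),
                            integer(1)),
        cumulative_energy = vapply(grid, function(r) {
          sum(d$energy[d$min_distance <= r])
        }, numeric(1))
      )
    }) |>
    ungroup()
  new_shell_profile(prof, threshold)
}

#' Converged pocket radius under the relative-stability rule
#'
#' Walks the shell grid and returns the smallest radius `r_k` whose
#' successive total satisfies `|E_{k+1} - E_k| / |E_{k+1}| < threshold`
#' with `E_{k+1} != 0`. The denominator is the newer total; the convention
#' is recorded on the profile. Returns `NA` when the rule is never met.
#'
#' @param profile a `shell_profile` (single dielectric) or a tibble with
#'   `radius` and `cumulative_energy` columns; a multi-dielectric profile
#'   yields one radius per dielectric.
#' @param threshold stability fraction in (0, 1); default 0.10.
#' @return converged radius in A (scalar, or a tibble for several
#'   dielectrics).
#' @export
detect_convergence <- function(profile, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  one <- function(df) {
    e <- df$cumulative_energy
    r <- df$radius
    if (length(e) < 2) {
      abort("need at least two grid points to assess convergence",
            class = "mfcc_insufficient_data")
    }
    for (k in seq_len(length(e) - 1)) {
      if (e[k + 1] != 0 && abs(e[k + 1] - e[k]) / abs(e[k + 1]) < threshold) {
        return(r[k])
      }
    }
    NA_real_
  }
  if ("dielectric" %in% names(profile) &&
      length(unique(profile$dielectric)) > 1) {
    profile |>
      group_by(.data$dielectric) |>
      group_modify(~ tibble(converged_radius = one(.x))) |>
      ungroup()
  } else {
    one(profile)
  }
}

#' @export
autoplot.shell_profile <- function(object, ...) {
  df <- as_tibble(object)
  if (!"dielectric" %in% names(df)) df$dielectric <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius,
                                   y = .data$cumulative_energy,
                                   colour = factor(.data$dielectric))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pocket radius r (Å)",
                  y = "total binding energy (kcal/mol)",
                  colour = "dielectric") +
    ggplot2::theme_minimal()
}
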