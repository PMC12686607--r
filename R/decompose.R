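# Four-term fragment combination and pocket-wide decomposition:
#   E(L-R_i) = E(L_CRC) - E(L_CC) - E(CRC) + E(CC)
# Negative energies are attractive, positive repulsive.

#' Per-residue interaction energy from the four fragment terms
#'
#' Combines the four fragment-system energies as
#' `E(L_CRC) - E(L_CC) - E(CRC) + E(CC)`. For a strictly pairwise-additive
#' backend the cap contributions cancel algebraically and the result equals
#' the direct ligand-residue(+waters) pairwise interaction sum.
#'
#' @param systems named list of the four `fragment_system`s
#'   (see [build_fragment_systems()]).
#' @param backend a classical `backend_spec`.
#' @return interaction energy in kcal/mol.
#' @export
mfcc_energy <- function(systems, backend = backend_classical()) {
  need <- c("L_CRC", "L_CC", "CRC", "CC")
  if (!all(need %in% names(systems))) {
    abort(paste0("fragment systems must contain terms: ",
                 paste(need, collapse = ", ")))
  }
  ev <- function(term) {
    tryCatch(evaluate_classical(systems[[term]], backend),
             error = function(e) {
               abort(paste0("energy evaluation failed for term ", term, ": ",
                            conditionMessage(e)), parent = e)
             })
  }
  combine_mfcc_terms(ev("L_CRC"), ev("L_CC"), ev("CRC"), ev("CC"))
}

#' Combine four already-evaluated term energies
#'
#' @param e_l_crc,e_l_cc,e_crc,e_cc term energies in kcal/mol.
#' @return `e_l_crc - e_l_cc - e_crc + e_cc`.
#' @export
combine_mfcc_terms <- function(e_l_crc, e_l_cc, e_crc, e_cc) {
  e_l_crc - e_l_cc - e_crc + e_cc
}

#' Annotate a record with its nearest ligand atom and region
#'
#' Finds the ligand atom closest to any atom of the record's residue, the
#' corresponding minimum distance, and -- when a region map is given -- the
#' ligand region of that atom. Distance ties are broken by the lower ligand
#' atom index.
#'
#' @param record one-row energy record (must carry `resid`).
#' @param structure atom tibble.
#' @param ligand_id ligand residue id.
#' @param region_map optional tibble `atom` -> `region` covering all ligand
#'   heavy atoms; a gap raises an annotation error.
#' @return the record with `min_distance`, `nearest_ligand_atom` and
#'   `contact_region` filled in.
#' @export
annotate_contact <- function(record, structure, ligand_id,
                             region_map = NULL) {
  lig <- res_atoms(structure, ligand_id)
  res <- res_atoms(structure, record$resid[1])
  lx <- as.matrix(lig[, c("x", "y", "z")])
  rx <- as.matrix(res[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rep(1, nrow(rx))) +
    outer(rep(1, nrow(lx)), rowSums(rx^2)) - 2 * lx %*% t(rx)
  dmin_per_lig <- sqrt(pmax(apply(d2, 1, min), 0))
  j <- which.min(dmin_per_lig)  # lowest index wins ties
  record$min_distance <- dmin_per_lig[j]
  record$nearest_ligand_atom <- lig$atom[j]
  if (!is.null(region_map)) {
    heavy <- lig$element != "H"
    gap <- setdiff(lig$atom[heavy], region_map$atom)
    if (length(gap) > 0) {
      abort(paste0("region map does not cover ligand atom(s): ",
                   paste(gap, collapse = ", ")),
            class = "mfcc_annotation_error")
    }
    # regions are defined over heavy atoms; when a hydrogen is nearest the
    # region of the nearest heavy atom is reported
    jh <- which(heavy)[which.min(dmin_per_lig[heavy])]
    record$contact_region <-
      region_map$region[match(lig$atom[jh], region_map$atom)]
  } else {
    record$contact_region <- NA_character_
  }
  record
}

#' Decompose a binding pocket into per-residue interaction energies
#'
#' Runs the full per-residue pipeline over every protein residue within
#' `r_max` of the ligand: conjugated-cap construction, water attachment,
#' four-term fragment assembly, classical energy evaluation at each
#' dielectric, contact annotation, then the cumulative shell profile and
#' its converged radius. Per-residue failures are collected; the run aborts
#' only when more than `failure_budget` of the pocket fails.
#'
#' @param structure hydrogen-complete atom tibble with charges (see
#'   [assign_protonation()]).
#' @param ligand_id ligand residue id; defaults to the first ligand.
#' @param r_max pocket radius in A (default 10).
#' @param dielectrics dielectric constants to evaluate (default 10 and 40).
#' @param backend backend spec; only `classical_pairwise` is evaluated
#'   directly (use [run_pipeline()] with a `qm_deck` backend to emit decks).
#' @param hbond_dmax water-attachment distance cutoff in A.
#' @param atom_mode shell distance criterion (see [select_shell()]).
#' @param region_map optional ligand region map (`atom`, `region`).
#' @param threshold shell-stability threshold.
#' @param failure_budget maximum tolerated fraction of failed residues.
#' @return an `mfcc_decomposition` object; `tidy()` gives the per-residue
#'   records, `glance()` per-dielectric totals and converged radii.
#' @export
decompose_pocket <- function(structure, ligand_id = NULL, r_max = 10,
                             dielectrics = c(10, 40),
                             backend = backend_classical(),
                             hbond_dmax = 3.5, atom_mode = "all_atoms",
                             region_map = NULL, threshold = 0.10,
                             failure_budget = 0.10) {
  rt <- residue_table(structure)
  if (is.null(ligand_id)) {
    ligs <- rt$resid[rt$role == "ligand"]
    if (length(ligs) == 0) abort("structure contains no ligand residue")
    ligand_id <- ligs[1]
  }
  if (!identical(backend$kind, "classical_pairwise")) {
    abort("decompose_pocket evaluates classical backends only; use run_pipeline() to emit QM decks")
  }
  pocket <- select_shell(structure, ligand_id, r_max, atom_mode = atom_mode)
  if (length(pocket) == 0) {
    empty <- tibble(resid = character(), chain = character(),
                    resno = integer(), resname = character(),
                    energy = numeric(), dielectric = numeric(),
                    min_distance = numeric(),
                    nearest_ligand_atom = character(),
                    contact_region = character(), waters = list())
    return(new_mfcc_decomposition(empty, NULL, structure, ligand_id,
                                  backend, list()))
  }
  wmap <- assign_waters(structure, pocket, hbond_dmax)
  failures <- list()
  recs <- list()
  for (id in pocket) {
    w <- wmap$water[!is.na(wmap$residue) & wmap$residue == id]
    rec <- tryCatch({
      capped <- build_caps(structure, id, waters = w)
      systems <- build_fragment_systems(capped, ligand_id, structure)
      one <- map(dielectrics, function(eps) {
        e <- mfcc_energy(systems, set_dielectric(backend, eps))
        tibble(resid = id, energy = e, dielectric = eps)
      }) |> list_rbind()
      one$waters <- rep(list(w), nrow(one))
      one
    }, error = function(e) {
      failures[[id]] <<- conditionMessage(e)
      NULL
    })
    recs[[id]] <- rec
  }
  if (length(failures) > length(pocket) * failure_budget) {
    abort(paste0(length(failures), " of ", length(pocket),
                 " pocket residues failed (budget ",
                 round(100 * failure_budget), "%); first error: ",
                 failures[[1]]))
  }
  records <- list_rbind(unname(recs))
  meta <- rt[match(records$resid, rt$resid),
             c("chain", "resno", "resname")]
  records <- bind_cols(records[, "resid"], meta,
                       records[, setdiff(names(records), "resid")])

  # contact annotation (one pass per residue)
  ann <- records |>
    distinct(.data$resid) |>
    group_by(.data$resid) |>
    group_modify(function(d, key) {
      r <- annotate_contact(tibble(resid = key$resid), structure,
                            ligand_id, region_map)
      r[, c("min_distance", "nearest_ligand_atom", "contact_region")]
    }) |>
    ungroup()
  records <- records |> left_join(ann, by = "resid")

  profile <- shell_sweep(records, structure, ligand_id, r_max,
                         atom_mode = atom_mode, threshold = threshold)
  new_mfcc_decomposition(records, profile, structure, ligand_id, backend,
                         failures)
}

new_mfcc_decomposition <- function(records, profile, structure, ligand_id,
                                   backend, failures) {
  structure(list(records = records, profile = profile,
                 ligand_id = ligand_id, backend = backend,
                 failures = failures,
                 n_pocket = length(unique(records$resid)),
                 title = attr(structure, "title")),
            class = "mfcc_decomposition")
}

#' @export
print.mfcc_decomposition <- function(x, ...) {
  cat("<mfcc_decomposition> ligand ", x$ligand_id, ", ",
      x$n_pocket, " pocket residues\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname decompose_pocket
#' @param x an `mfcc_decomposition`.
#' @param ... unused.
#' @export
tidy.mfcc_decomposition <- function(x, ...) {
  x$records
}

#' @rdname decompose_pocket
#' @export
glance.mfcc_decomposition <- function(x, ...) {
  if (nrow(x$records) == 0) {
    return(tibble(dielectric = numeric(), total_energy = numeric(),
                  converged_radius = numeric(), n_residues = integer(),
                  n_failures = integer()))
  }
  conv <- detect_convergence(x$profile,
                             attr(x$profile, "threshold") %||% 0.10)
  if (!is.data.frame(conv)) {
    conv <- tibble(dielectric = unique(x$records$dielectric),
                   converged_radius = conv)
  }
  x$records |>
    group_by(.data$dielectric) |>
    summarise(total_energy = sum(.data$energy),
              n_residues = n(), .groups = "drop") |>
    left_join(conv, by = "dielectric") |>
    mutate(n_failures = length(x$failures)) |>
    select("dielectric", "total_energy", "converged_radius",
           "n_residues", "n_failures")
}

#' Rank pocket residues by interaction energy
#'
#' Splits the records into attractive (negative) residues sorted most
#' attractive first and repulsive (positive) residues sorted most repulsive
#' first, for one dielectric. Zero-energy residues keep input order at the
#' end of the attractive block.
#'
#' @param records per-residue record tibble (from `tidy()`), or an
#'   `mfcc_decomposition`.
#' @param dielectric dielectric to rank at; defaults to the largest present
#'   (the study reports its ranking at the higher screening value).
#' @return tibble with a `classification` column (`attractive`/`repulsive`)
#'   and attribute `total_energy` (named by dielectric).
#' @export
rank_residues <- function(records, dielectric = NULL) {
  if (inherits(records, "mfcc_decomposition")) records <- tidy(records)
  if (nrow(records) == 0) abort("cannot rank an empty record table")
  totals <- records |>
    group_by(.data$dielectric) |>
    summarise(total = sum(.data$energy), .groups = "drop")
  if (!is.null(dielectric)) {
    records <- records[records$dielectric == dielectric, ]
  } else if ("dielectric" %in% names(records) &&
             length(unique(records$dielectric)) > 1) {
    records <- records[records$dielectric == max(records$dielectric), ]
  }
  att <- records[records$energy <= 0, ]
  att <- att[order(att$energy), ]
  rep_ <- records[records$energy > 0, ]
  rep_ <- rep_[order(-rep_$energy), ]
  out <- bind_rows(
    mutate(att, classification = "attractive"),
    mutate(rep_, classification = "repulsive")
  )
  attr(out, "total_energy") <- setNames(totals$total, totals$dielectric)
  out
}

#' @export
autoplot.mfcc_decomposition <- function(object, dielectric = NULL,
                                        top_n = 15, ...) {
  rk <- rank_residues(object, dielectric)
  rk <- head(rk[order(-abs(rk$energy)), ], top_n)
  rk$label <- paste0(rk$resname, rk$resno)
  ggplot2::ggplot(rk, ggplot2::aes(
    x = .data$energy,
    y = stats::reorder(.data$label, -.data$energy),
    fill = .data$classification
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "interaction energy (kcal/mol)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
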