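# Conjugated-cap fragmentation. For residue R_i the caps C_{i-1} and
# C_{i+1} are the entire covalently adjacent residues; the two outer
# peptide bonds are cut and the dangling valences saturated with hydrogens
# placed along the former bond vector at standard lengths (N-H 1.01 A,
# C-H 1.09 A). The four fragment systems combined by the decomposition are
#   L-CRC (ligand + caps + residue + its waters), L-CC, CRC, CC,
# where the CC-type terms replace R_i by two saturation hydrogens on the
# newly exposed cap bonds.

SAT_NH <- 1.01
SAT_CH <- 1.09

# a saturation hydrogen replacing `removed` along the former bond from `host`
saturation_h <- function(host_row, removed_pos, blen, saturates) {
  host <- as.numeric(host_row[, c("x", "y", "z")])
  pos <- host + blen * unitv(removed_pos - host)
  tibble(
    chain = host_row$chain, resno = host_row$resno,
    inscode = host_row$inscode, resname = host_row$resname,
    role = host_row$role, atom = "Hcap", element = "H",
    x = pos[1], y = pos[2], z = pos[3],
    charge = 0, occ = 1, altloc = "", added_h = TRUE, sat_h = TRUE,
    resid = host_row$resid, saturates = saturates
  )
}

atom_pos <- function(structure, id, name) {
  r <- structure[structure$resid == id & structure$atom == name, ]
  if (nrow(r) == 0) return(NULL)
  as.numeric(r[1, c("x", "y", "z")])
}

#' Build the conjugated-cap system of one residue
#'
#' Excises residue `residue_id` together with its two chain-adjacent cap
#' residues (whole residues, including side chains). The two outer peptide
#' bonds -- between the N-side cap and residue i-2, and the C-side cap and
#' residue i+2 -- are cut and saturated with hydrogens along the former
#' bond vectors. At chain termini the corresponding cap is empty and the
#' real terminal groups are retained.
#'
#' @param structure hydrogen-complete atom tibble.
#' @param residue_id residue key (`"chain:resno:inscode"`).
#' @param waters character vector of water residue ids attached to this
#'   residue (see [assign_waters()]).
#' @return a `capped_residue` object: list with the residue atoms, cap
#'   atoms, saturation hydrogens (with provenance), and attached waters.
#' @export
build_caps <- function(structure, residue_id, waters = character()) {
  rt <- residue_table(structure)
  r <- rt[rt$resid == residue_id, ]
  if (nrow(r) == 0) abort(paste0("residue not found: ", residue_id))
  if (r$role != "protein") abort("caps are defined for protein residues only")
  res <- res_atoms(structure, residue_id)
  if (!all(c("N", "CA", "C") %in% res$atom)) {
    abort(paste0("incomplete backbone for ", residue_id))
  }

  adj <- protein_adjacency(structure)
  a <- adj[adj$resid == residue_id, ]
  prev_id <- a$prev
  next_id <- a$nxt

  cap_prev <- if (!is.na(prev_id)) res_atoms(structure, prev_id) else NULL
  cap_next <- if (!is.na(next_id)) res_atoms(structure, next_id) else NULL

  cap_h <- list()
  if (!is.na(prev_id)) {
    pp <- adj[adj$resid == prev_id, ]
    if (!is.na(pp$prev)) {
      # cut N(i-1) -- C(i-2)
      host <- cap_prev[cap_prev$atom == "N", ][1, ]
      removed <- atom_pos(structure, pp$prev, "C")
      cap_h$prev <- saturation_h(host, removed, SAT_NH,
                                 paste0("N(", prev_id, ")-C(", pp$prev, ")"))
    }
  }
  if (!is.na(next_id)) {
    nn <- adj[adj$resid == next_id, ]
    if (!is.na(nn$nxt)) {
      # cut C(i+1) -- N(i+2)
      host <- cap_next[cap_next$atom == "C", ][1, ]
      removed <- atom_pos(structure, nn$nxt, "N")
      cap_h$nxt <- saturation_h(host, removed, SAT_CH,
                                paste0("C(", next_id, ")-N(", nn$nxt, ")"))
    }
  }

  structure(list(
    residue_id = residue_id,
    residue = res,
    cap_prev = cap_prev,
    cap_next = cap_next,
    cap_hydrogens = bind_rows(cap_h),
    attached_waters = waters
  ), class = "capped_residue")
}

#' @export
print.capped_residue <- function(x, ...) {
  cat("<capped_residue> ", x$residue_id, " (", x$residue$resname[1], ")\n",
      sep = "")
  cat("  cap_prev: ", if (is.null(x$cap_prev)) "none" else
    x$cap_prev$resid[1], "\n", sep = "")
  cat("  cap_next: ", if (is.null(x$cap_next)) "none" else
    x$cap_next$resid[1], "\n", sep = "")
  cat("  saturation hydrogens: ", nrow(x$cap_hydrogens), "\n", sep = "")
  cat("  attached waters: ", length(x$attached_waters), "\n", sep = "")
  invisible(x)
}

#' Assign crystallographic waters to pocket residues
#'
#' Each water is attached to at most one pocket residue: the residue with
#' the smallest donor-acceptor heavy-atom distance (water oxygen to any
#' polar N/O/S atom of the residue) among all residues within
#' `hbond_dmax`. Waters with no qualifying residue are left unassigned.
#'
#' @param structure atom tibble.
#' @param pocket character vector of pocket residue ids.
#' @param hbond_dmax maximum donor-acceptor heavy-atom distance in A.
#' @return tibble with one row per water: `water`, `residue` (NA when
#'   unassigned), `distance`.
#' @export
assign_waters <- function(structure, pocket, hbond_dmax = 3.5) {
  rt <- residue_table(structure)
  waters <- rt$resid[rt$role == "water"]
  if (length(waters) == 0 || length(pocket) == 0) {
    return(tibble(water = waters, residue = NA_character_,
                  distance = NA_real_))
  }
  polar <- structure |>
    filter(.data$resid %in% pocket, .data$element %in% c("N", "O", "S"))
  out <- map(waters, function(w) {
    o <- structure |> filter(.data$resid == w, .data$element == "O")
    if (nrow(o) == 0) {
      return(tibble(water = w, residue = NA_character_, distance = NA_real_))
    }
    dv <- sqrt((polar$x - o$x[1])^2 + (polar$y - o$y[1])^2 +
                 (polar$z - o$z[1])^2)
    per_res <- tibble(residue = polar$resid, d = dv) |>
      group_by(.data$residue) |>
      summarise(d = min(.data$d), .groups = "drop") |>
      filter(.data$d <= hbond_dmax) |>
      arrange(.data$d, match(.data$residue, pocket))
    if (nrow(per_res) == 0) {
      tibble(water = w, residue = NA_character_, distance = NA_real_)
    } else {
      tibble(water = w, residue = per_res$residue[1],
             distance = per_res$d[1])
    }
  })
  list_rbind(out)
}

fragment_system <- function(atoms, term, multiplicity = 1L) {
  atoms <- as_tibble(atoms)
  nc <- if (anyNA(atoms$charge)) NA_integer_ else
    as.integer(round(sum(atoms$charge)))
  structure(atoms,
            class = c("fragment_system", class(tibble())),
            term = term, net_charge = nc, multiplicity = multiplicity)
}

#' @export
print.fragment_system <- function(x, ...) {
  cat("<fragment_system> term=", attr(x, "term"),
      " atoms=", nrow(x),
      " net_charge=", attr(x, "net_charge"),
      " multiplicity=", attr(x, "multiplicity"), "\n", sep = "")
  NextMethod()
}

#' Build the four MFCC fragment systems of a residue
#'
#' Assembles the four atom sets whose energies combine to the per-residue
#' interaction energy: `L_CRC` (ligand + caps + residue + attached waters),
#' `L_CC` (ligand + caps), `CRC` (caps + residue + waters) and `CC`
#' (caps alone). In the two CC-type systems the residue is removed and the
#' newly exposed cap bonds -- the C-side carbonyl carbon of the N-cap and
#' the amide nitrogen of the C-cap -- are hydrogen-saturated by the same
#' bond-vector rule used for the outer cuts. Attached waters travel with
#' the residue: they are present exactly when the residue is present.
#'
#' @param capped a `capped_residue` (see [build_caps()]).
#' @param ligand_id ligand residue id.
#' @param structure the full atom tibble the capped residue came from.
#' @return named list of four `fragment_system` objects
#'   (`L_CRC`, `L_CC`, `CRC`, `CC`).
#' @export
build_fragment_systems <- function(capped, ligand_id, structure) {
  lig <- res_atoms(structure, ligand_id)
  if (nrow(lig) == 0) abort(paste0("ligand not found: ", ligand_id))
  if (lig$role[1] != "ligand") abort(paste0(ligand_id, " is not a ligand"))
  res <- capped$residue
  wat <- if (length(capped$attached_waters) > 0) {
    structure |> filter(.data$resid %in% capped$attached_waters)
  } else {
    NULL
  }
  caps <- bind_rows(capped$cap_prev, capped$cap_next)
  outer_h <- capped$cap_hydrogens
  if (nrow(caps) == 0) {
    abort(paste0("residue ", capped$residue_id,
                 " has no caps; fragment systems are undefined"),
          class = "mfcc_integrity_error")
  }

  # inner saturation hydrogens for the CC-type systems
  inner <- list()
  if (!is.null(capped$cap_prev)) {
    host <- capped$cap_prev[capped$cap_prev$atom == "C", ][1, ]
    n_pos <- as.numeric(res[res$atom == "N", ][1, c("x", "y", "z")])
    inner$prev <- saturation_h(host, n_pos, SAT_CH,
                               paste0("C(", capped$cap_prev$resid[1], ")-N(",
                                      capped$residue_id, ")"))
  }
  if (!is.null(capped$cap_next)) {
    host <- capped$cap_next[capped$cap_next$atom == "N", ][1, ]
    c_pos <- as.numeric(res[res$atom == "C", ][1, c("x", "y", "z")])
    inner$nxt <- saturation_h(host, c_pos, SAT_NH,
                              paste0("N(", capped$cap_next$resid[1], ")-C(",
                                     capped$residue_id, ")"))
  }
  inner_h <- bind_rows(inner)

  drop_prov <- function(df) {
    if (!is.null(df) && "saturates" %in% names(df)) df$saturates <- NULL
    df
  }
  crc_atoms <- bind_rows(caps, drop_prov(outer_h), res, wat)
  cc_atoms <- bind_rows(caps, drop_prov(outer_h), drop_prov(inner_h))

  list(
    L_CRC = fragment_system(bind_rows(lig, crc_atoms), "L_CRC"),
    L_CC = fragment_system(bind_rows(lig, cc_atoms), "L_CC"),
    CRC = fragment_system(crc_atoms, "CRC"),
    CC = fragment_system(cc_atoms, "CC")
  )
}
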