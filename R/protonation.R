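# Hydrogen completion and partial-charge assignment at fixed pH-7.4 rules:
# ASP/GLU side chains deprotonated (-1), LYS/ARG protonated (+1), HIS
# neutral N-epsilon tautomer unless overridden, termini zwitterionic by
# default. Hydrogens are rebuilt at idealized local geometry from the
# residue topology templates; partial charges follow a simple per-atom
# scheme renormalized so every residue sums exactly to its formal charge.

# map of protein chain adjacency; resno gaps > 1 are chain breaks (treated
# as termini), a consecutive pair further than `bond_max` is an error.
protein_adjacency <- function(structure, bond_max = 2.0) {
  prot <- residue_table(structure) |> filter(.data$role == "protein")
  if (nrow(prot) == 0) {
    return(tibble(resid = character(), prev = character(), nxt = character()))
  }
  prot <- prot |> arrange(.data$chain, .data$resno, .data$inscode)
  prev <- rep(NA_character_, nrow(prot))
  nxt <- rep(NA_character_, nrow(prot))
  for (i in seq_len(nrow(prot) - 1)) {
    a <- prot[i, ]
    b <- prot[i + 1, ]
    if (a$chain != b$chain) next
    ca <- res_atoms(structure, a$resid)
    cb <- res_atoms(structure, b$resid)
    cpos <- ca[ca$atom == "C", c("x", "y", "z")]
    npos <- cb[cb$atom == "N", c("x", "y", "z")]
    if (nrow(cpos) == 0 || nrow(npos) == 0) next
    d <- vnorm(as.numeric(cpos) - as.numeric(npos))
    if (d <= bond_max) {
      nxt[i] <- b$resid
      prev[i + 1] <- a$resid
    } else if (b$resno - a$resno <= 1) {
      abort(paste0("chain discontinuity: peptide bond ", a$resid, " -> ",
                   b$resid, " is ", round(d, 2), " A"),
            class = "mfcc_chain_discontinuity")
    }
  }
  tibble(resid = prot$resid, prev = prev, nxt = nxt)
}

h_names_for <- function(parent, count, terminal_n = FALSE) {
  if (parent == "N") {
    if (terminal_n || count > 1) return(paste0("H", seq_len(count)))
    return("H")
  }
  if (parent == "CA" && count == 2) return(c("HA2", "HA3"))
  if (parent == "OXT") return("HXT")
  base <- sub("^.", "", parent)
  if (count == 1) paste0("H", base) else paste0("H", base, seq_len(count))
}

heavy_base_charge <- function(atom, element, nh, resname) {
  if (atom == "N") return(-0.47)
  if (atom == "CA") return(if (resname == "GLY") -0.02 else 0.07)
  if (atom == "C") return(0.51)
  if (atom %in% c("O", "OXT")) return(-0.51)
  switch(element,
    C = -0.09 * nh,
    O = if (nh >= 1) -0.66 else -0.60,
    N = if (nh == 3) -0.30 else -0.62,
    S = if (nh >= 1) -0.23 else -0.10,
    0
  )
}

h_charge_on <- function(parent_element) {
  switch(parent_element, C = 0.09, N = 0.31, O = 0.43, S = 0.16, 0.09)
}

# replicate a 1-row residue identity block alongside new atom fields
with_proto <- function(proto, ...) {
  new <- tibble(...)
  bind_cols(proto[rep(1, nrow(new)), , drop = FALSE], new)
}

# protonate one protein residue; returns list(atoms, formal)
protonate_residue <- function(res_df, topo, prev_c, next_n, termini) {
  resname <- res_df$resname[1]
  heavy <- res_df[res_df$element != "H", , drop = FALSE]

  required <- setdiff(topo$heavy, "OXT")
  missing <- setdiff(required, heavy$atom)
  if (length(missing) > 0) {
    abort(paste0("residue ", res_df$resid[1], " (", resname,
                 ") is missing heavy atoms: ",
                 paste(missing, collapse = ", ")),
          class = "mfcc_missing_atoms")
  }

  is_nterm <- is.null(prev_c)
  is_cterm <- is.null(next_n)

  pos <- as.matrix(heavy[, c("x", "y", "z")])
  rownames(pos) <- heavy$atom

  # C-terminal carboxylate: complete OXT if the file lacks it
  added_oxt <- FALSE
  if (is_cterm && !"OXT" %in% heavy$atom) {
    oxt <- complete_positions(pos["C", ], rbind(pos["CA", ], pos["O", ]),
                              1, geom = "sp2", blen = 1.25)
    pos <- rbind(pos, OXT = oxt[1, ])
    added_oxt <- TRUE
  }

  # bonded-neighbour map (within residue + peptide links)
  nbr <- list()
  add_bond <- function(nbr, a, b) {
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
    nbr
  }
  for (i in seq_len(nrow(topo$bonds))) {
    a <- topo$bonds[i, 1]; b <- topo$bonds[i, 2]
    if (a %in% rownames(pos) && b %in% rownames(pos)) nbr <- add_bond(nbr, a, b)
  }
  if ("OXT" %in% rownames(pos)) nbr <- add_bond(nbr, "C", "OXT")

  # hydrogen counts, with terminus adjustments
  hyd <- topo$hyd
  formal <- topo$sc_charge
  if (is_nterm) {
    if (termini == "zwitterionic") {
      hyd$nh[hyd$atom == "N"] <- if (resname == "PRO") 2L else 3L
      hyd$geom[hyd$atom == "N"] <- "sp3"
      formal <- formal + 1
    } else {
      hyd$nh[hyd$atom == "N"] <- if (resname == "PRO") 1L else 2L
      hyd$geom[hyd$atom == "N"] <- "sp3"
    }
  }
  if (is_cterm) {
    if (termini == "zwitterionic") {
      formal <- formal - 1
    } else {
      hyd <- bind_rows(hyd, tibble(atom = "OXT", nh = 1L, geom = "sp3"))
    }
  }

  ext <- list()  # inter-residue neighbour positions
  if (!is_nterm) ext[["N"]] <- prev_c
  if (!is_cterm) ext[["C"]] <- next_n

  h_rows <- list()
  for (j in seq_len(nrow(hyd))) {
    an <- hyd$atom[j]
    n_h <- hyd$nh[j]
    if (n_h == 0 || !an %in% rownames(pos)) next
    nb_names <- nbr[[an]] %||% character()
    nbrs <- pos[nb_names, , drop = FALSE]
    if (!is.null(ext[[an]])) nbrs <- rbind(nbrs, ext[[an]])
    ref <- NULL
    if (nrow(nbrs) == 1) {
      b <- nb_names[1]
      ref_cand <- setdiff(nbr[[b]] %||% character(), an)
      if (length(ref_cand) > 0) {
        ref <- pos[ref_cand[1], ]
      } else if (!is.null(ext[[b]])) {
        ref <- ext[[b]]
      } else {
        abort(paste0("no reference atom to orient hydrogens on ", an,
                     " of ", res_df$resid[1]))
      }
    }
    el <- element_of(an)
    hp <- complete_positions(pos[an, ], nbrs, n_h, geom = hyd$geom[j],
                             ref = ref, blen = h_bond_length(el))
    nm <- h_names_for(an, n_h, terminal_n = is_nterm && an == "N")
    h_rows[[an]] <- tibble(atom = nm, parent = an, parent_el = el,
                           x = hp[, 1], y = hp[, 2], z = hp[, 3])
  }
  hs <- bind_rows(h_rows)

  proto <- res_df[1, c("chain", "resno", "inscode", "resname", "role",
                       "resid")]
  out_heavy <- heavy
  out_heavy$added_h <- FALSE
  if (added_oxt) {
    out_heavy <- bind_rows(out_heavy, with_proto(
      proto, atom = "OXT", element = "O",
      x = pos["OXT", 1], y = pos["OXT", 2], z = pos["OXT", 3],
      charge = NA_real_, occ = 1, altloc = "", added_h = TRUE, sat_h = FALSE
    ))
  }
  out_h <- if (nrow(hs) > 0) {
    with_proto(proto, atom = hs$atom, element = "H",
               x = hs$x, y = hs$y, z = hs$z,
               charge = NA_real_, occ = 1, altloc = "", added_h = TRUE,
               sat_h = FALSE)
  } else {
    NULL
  }

  atoms <- bind_rows(out_heavy, out_h)

  # charges: base scheme, then uniform renormalization to the formal charge
  nh_of <- setNames(rep(0L, nrow(atoms)), atoms$atom)
  for (j in seq_len(nrow(hyd))) nh_of[hyd$atom[j]] <- hyd$nh[j]
  q <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    if (atoms$element[i] == "H") {
      pe <- hs$parent_el[match(atoms$atom[i], hs$atom)]
      q[i] <- h_charge_on(pe)
    } else {
      q[i] <- heavy_base_charge(atoms$atom[i], atoms$element[i],
                                unname(nh_of[atoms$atom[i]]), resname)
    }
  }
  q <- q + (formal - sum(q)) / length(q)
  atoms$charge <- q
  list(atoms = atoms, formal = formal)
}

#' Add hydrogens and partial charges at fixed pH rules
#'
#' Applies simple pH-7.4 protonation rules to every protein residue:
#' ASP/GLU side chains deprotonated (formal charge -1), LYS/ARG protonated
#' (+1), histidines in the neutral N-epsilon tautomer unless overridden via
#' `his_states`, and chain termini zwitterionic (default) or neutral.
#' Existing protein/water hydrogens are discarded and rebuilt at idealized
#' local geometry; every added atom is flagged in `added_h`. A missing
#' C-terminal OXT is completed in the carboxylate plane. Water molecules are
#' rebuilt as 3-site waters; ions receive their nominal charges; ligand
#' atoms are kept untouched (their hydrogens are expected on input) and
#' their charges, when absent, are filled from element defaults and
#' renormalized to `ligand_charge`.
#'
#' Partial charges follow a minimal per-atom scheme (backbone amide values,
#' element/valence rules for side chains) and are renormalized uniformly
#' within each residue so they sum exactly to the residue's formal charge.
#'
#' @param structure atom tibble (see [read_pdb()]).
#' @param ph solution pH; only 7.4-rule behaviour is implemented and values
#'   far from 7.4 are rejected.
#' @param his_states optional named character vector `resid -> state` with
#'   states `"HIE"`, `"HID"` or `"HIP"`.
#' @param termini `"zwitterionic"` (NH3+/COO-) or `"neutral"` (NH2/COOH).
#' @param rebuild optional function `(structure, resid) -> structure` called
#'   to repair residues with missing heavy atoms before protonation.
#' @param ligand_charge total formal charge assumed for each ligand residue
#'   whose atoms carry no input charges.
#' @return atom tibble with hydrogens, charges, and `added_h` flags.
#' @export
assign_protonation <- function(structure, ph = 7.4, his_states = NULL,
                               termini = c("zwitterionic", "neutral"),
                               rebuild = NULL, ligand_charge = 0) {
  termini <- match.arg(termini)
  if (abs(ph - 7.4) > 1.5) {
    abort("only pH ~7.4 rule-based protonation is implemented")
  }
  structure <- as_structure_tbl(structure)
  rt <- residue_table(structure)
  adj <- protein_adjacency(structure)

  pieces <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    r <- rt[i, ]
    res_df <- res_atoms(structure, r$resid)
    if (r$role == "protein") {
      st <- if (!is.null(his_states) && r$resid %in% names(his_states)) {
        his_states[[r$resid]]
      } else {
        "HIE"
      }
      topo <- res_topology(r$resname, his_state = st)
      heavy <- res_df[res_df$element != "H", ]
      missing <- setdiff(setdiff(topo$heavy, "OXT"), heavy$atom)
      if (length(missing) > 0 && !is.null(rebuild)) {
        res_df <- rebuild(res_df, r$resid)
      }
      a <- adj[adj$resid == r$resid, ]
      prev_c <- NULL
      next_n <- NULL
      if (!is.na(a$prev)) {
        p <- res_atoms(structure, a$prev)
        prev_c <- as.numeric(p[p$atom == "C", c("x", "y", "z")])
      }
      if (!is.na(a$nxt)) {
        nx <- res_atoms(structure, a$nxt)
        next_n <- as.numeric(nx[nx$atom == "N", c("x", "y", "z")])
      }
      pieces[[i]] <- protonate_residue(res_df, topo, prev_c, next_n,
                                       termini)$atoms
    } else if (r$role == "water") {
      o <- res_df[res_df$element == "O", ][1, ]
      if (is.na(o$atom)) {
        abort(paste0("water ", r$resid, " has no oxygen"))
      }
      hp <- complete_positions(as.numeric(o[, c("x", "y", "z")]), NULL, 2,
                               blen = 0.9572)
      proto <- o[, c("chain", "resno", "inscode", "resname", "role", "resid")]
      o$charge <- -0.834
      o$added_h <- FALSE
      pieces[[i]] <- bind_rows(
        o,
        with_proto(proto, atom = c("H1", "H2"), element = "H",
                   x = hp[, 1], y = hp[, 2], z = hp[, 3],
                   charge = 0.417, occ = 1, altloc = "", added_h = TRUE,
                   sat_h = FALSE)
      )
    } else if (r$role == "ion") {
      res_df$charge <- unname(.ION_CHARGES[toupper(r$resname)])
      pieces[[i]] <- res_df
    } else {
      # ligand: keep geometry/hydrogens; fill charges only when absent
      if (anyNA(res_df$charge)) {
        base <- dplyr::recode(res_df$element, O = -0.45, N = -0.40,
                              S = -0.20, H = 0.10, .default = 0)
        base <- base + (ligand_charge - sum(base)) / length(base)
        res_df$charge <- base
      }
      pieces[[i]] <- res_df
    }
  }
  out <- as_structure_tbl(bind_rows(pieces))
  attr(out, "title") <- attr(structure, "title")
  attr(out, "source") <- attr(structure, "source")
  out
}

#' Per-residue formal charges implied by the partial charges
#'
#' Because [assign_protonation()] renormalizes partial charges to sum
#' exactly to each residue's formal charge, rounding the per-residue sums
#' recovers the formal charges.
#'
#' @param structure atom tibble with charges.
#' @return tibble with `resid`, `resname`, `role`, `formal`.
#' @export
residue_formal_charges <- function(structure) {
  structure |>
    group_by(.data$resid) |>
    summarise(resname = first(.data$resname), role = first(.data$role),
              formal = round(sum(.data$charge)), .groups = "drop")
}
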