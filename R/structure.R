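# Structures are plain tibbles with one row per atom:
#   chain, resno, inscode, resname, role, atom, element, x, y, z,
#   charge, occ, altloc, added_h, sat_h, resid
# `role` is one of "protein", "ligand", "water", "ion". `resid` is the
# unique residue key "chain:resno:inscode". Reader/writer go through bio3d.

make_resid <- function(chain, resno, inscode) {
  paste(chain, resno, inscode, sep = ":")
}

structure_cols <- c("chain", "resno", "inscode", "resname", "role", "atom",
                    "element", "x", "y", "z", "charge", "occ", "altloc",
                    "added_h", "sat_h", "resid")

as_structure_tbl <- function(df) {
  df <- as_tibble(df)
  if (!"charge" %in% names(df)) df$charge <- NA_real_
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"altloc" %in% names(df)) df$altloc <- ""
  if (!"added_h" %in% names(df)) df$added_h <- FALSE
  if (!"sat_h" %in% names(df)) df$sat_h <- FALSE
  if (!"inscode" %in% names(df)) df$inscode <- ""
  df$resid <- make_resid(df$chain, df$resno, df$inscode)
  df[structure_cols]
}

assign_role <- function(resname, rectype, n_atoms) {
  resname <- toupper(resname)
  dplyr::case_when(
    resname %in% .AA3 ~ "protein",
    resname %in% .WATER_NAMES ~ "water",
    resname %in% names(.ION_CHARGES) & n_atoms == 1 ~ "ion",
    TRUE ~ "ligand"
  )
}

normalize_resname <- function(x) {
  x <- toupper(x)
  x[x %in% c("HID", "HIE", "HIP", "HSD", "HSE", "HSP")] <- "HIS"
  x
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records into an atom tibble, resolves alternate
#' locations to a single conformation, and assigns each residue a role:
#' standard amino acids are `protein`, HOH/WAT residues are `water`,
#' single-atom HETATM residues with a known ion name are `ion`, and all
#' remaining HETATM residues are `ligand`.
#'
#' @param path PDB file path.
#' @param altloc_policy `"highest_occupancy"` keeps, per atom, the alternate
#'   location with the largest occupancy (ties broken by label `A`);
#'   `"label_A"` keeps only blank or `A` locations.
#' @return atom tibble (one row per atom) with attributes `title` and
#'   `source`.
#' @export
read_pdb <- function(path, altloc_policy = c("highest_occupancy", "label_A")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  coord_idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in coord_idx) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      abort(paste0("malformed coordinate line ", i, " in ", path),
            class = "mfcc_parse_error")
    }
  }

  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  df <- tibble(
    rectype = at$type,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    inscode = ifelse(is.na(at$insert), "", at$insert),
    resname = normalize_resname(at$resid),
    atom = at$elety,
    element = {
      el <- toupper(ifelse(is.na(at$elesy) | at$elesy == "", NA, at$elesy))
      ifelse(is.na(el), element_of(at$elety), el)
    },
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  df$resid <- make_resid(df$chain, df$resno, df$inscode)

  # altloc resolution: one conformation per (residue, atom name)
  if (altloc_policy == "label_A") {
    df <- df[df$altloc %in% c("", "A"), ]
  }
  df$.row <- seq_len(nrow(df))
  df <- df |>
    group_by(.data$resid, .data$atom) |>
    arrange(desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.row)
  df$.row <- NULL

  n_per_res <- df |> count(.data$resid, name = "n_atoms")
  df <- df |> left_join(n_per_res, by = "resid")
  df$role <- assign_role(df$resname, df$rectype, df$n_atoms)
  # ATOM records of standard residues always protein, even if mislabelled
  df$role[df$rectype == "ATOM" & df$resname %in% .AA3] <- "protein"
  df$n_atoms <- NULL
  df$rectype <- NULL

  if (!any(df$role == "protein")) {
    abort(paste0("no protein residues found in ", path),
          class = "mfcc_content_error")
  }
  out <- as_structure_tbl(df)
  attr(out, "title") <- basename(path)
  attr(out, "source") <- list(kind = "file", path = path)
  out
}

#' Write a structure to a PDB file
#'
#' Protein residues are written as ATOM records; ligand, water and ion
#' residues as HETATM. Coordinates are written at PDB precision (1e-3 A).
#'
#' @param structure atom tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  s <- structure
  type <- ifelse(s$role == "protein", "ATOM", "HETATM")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    type = type,
    resno = s$resno,
    resid = s$resname,
    insert = ifelse(s$inscode == "", "", s$inscode),
    chain = s$chain,
    elety = s$atom,
    eleno = seq_len(nrow(s)),
    o = s$occ, b = rep(0, nrow(s)),
    elesy = s$element
  )
  invisible(path)
}

#' Export a fragment system as an XYZ file
#'
#' Standard XYZ: atom count, a comment line carrying the four-term label and
#' the net charge, then one `element x y z` line per atom with coordinates
#' printed to 8 decimals.
#'
#' @param system a `fragment_system` (see [build_fragment_systems()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_xyz <- function(system, path) {
  if (nrow(system) == 0) abort("refusing to write an empty fragment system")
  hdr <- sprintf("term=%s charge=%d multiplicity=%d",
                 attr(system, "term") %||% "fragment",
                 attr(system, "net_charge") %||% 0L,
                 attr(system, "multiplicity") %||% 1L)
  lines <- c(
    as.character(nrow(system)),
    hdr,
    sprintf("%-2s %14.8f %14.8f %14.8f", system$element,
            system$x, system$y, system$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file written by [write_fragment_xyz()]
#'
#' @param path XYZ file path.
#' @return tibble with columns `element`, `x`, `y`, `z`; the comment line is
#'   kept in attribute `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  out <- tibble(
    element = map_chr(parts, 1),
    x = as.numeric(map_chr(parts, 2)),
    y = as.numeric(map_chr(parts, 3)),
    z = as.numeric(map_chr(parts, 4))
  )
  attr(out, "comment") <- lines[2]
  out
}

#' Residue-level summary of a structure
#'
#' @param structure atom tibble.
#' @return tibble with one row per residue (`resid`, `chain`, `resno`,
#'   `inscode`, `resname`, `role`, `n_atoms`), in structure order.
#' @export
residue_table <- function(structure) {
  structure |>
    group_by(.data$resid) |>
    summarise(chain = first(.data$chain), resno = first(.data$resno),
              inscode = first(.data$inscode), resname = first(.data$resname),
              role = first(.data$role), n_atoms = n(), .groups = "drop") |>
    arrange(match(.data$resid, unique(structure$resid)))
}

# atoms of one residue
res_atoms <- function(structure, id) {
  structure[structure$resid == id, , drop = FALSE]
}
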