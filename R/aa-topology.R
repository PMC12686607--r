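# Residue topology templates for the 20 standard amino acids: heavy-atom
# bonds, hydrogen counts at pH 7.4, local geometry for hydrogen placement,
# and side-chain formal charges. Atom names follow PDB v3 conventions.
#
# These templates drive protonation (hydrogen completion), the per-atom
# charge scheme, and the synthetic peptide builder.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.WATER_NAMES <- c("HOH", "WAT", "TIP3", "SOL", "H2O")

.ION_CHARGES <- c(ZN = 2, MG = 2, CA = 2, "NA" = 1, K = 1, CL = -1, MN = 2,
                  FE = 2, CU = 2, BR = -1, IOD = -1, CD = 2, NI = 2)

# side-chain bonds (heavy atoms), one "A-B" string per bond
.SC_BONDS <- list(
  ALA = character(),
  ARG = c("CB-CG", "CG-CD", "CD-NE", "NE-CZ", "CZ-NH1", "CZ-NH2"),
  ASN = c("CB-CG", "CG-OD1", "CG-ND2"),
  ASP = c("CB-CG", "CG-OD1", "CG-OD2"),
  CYS = c("CB-SG"),
  GLN = c("CB-CG", "CG-CD", "CD-OE1", "CD-NE2"),
  GLU = c("CB-CG", "CG-CD", "CD-OE1", "CD-OE2"),
  GLY = character(),
  HIS = c("CB-CG", "CG-ND1", "CG-CD2", "ND1-CE1", "CD2-NE2", "CE1-NE2"),
  ILE = c("CB-CG1", "CB-CG2", "CG1-CD1"),
  LEU = c("CB-CG", "CG-CD1", "CG-CD2"),
  LYS = c("CB-CG", "CG-CD", "CD-CE", "CE-NZ"),
  MET = c("CB-CG", "CG-SD", "SD-CE"),
  PHE = c("CB-CG", "CG-CD1", "CG-CD2", "CD1-CE1", "CD2-CE2", "CE1-CZ", "CE2-CZ"),
  PRO = c("CB-CG", "CG-CD", "CD-N"),
  SER = c("CB-OG"),
  THR = c("CB-OG1", "CB-CG2"),
  TRP = c("CB-CG", "CG-CD1", "CG-CD2", "CD1-NE1", "NE1-CE2", "CD2-CE2",
          "CD2-CE3", "CE3-CZ3", "CZ3-CH2", "CH2-CZ2", "CZ2-CE2"),
  TYR = c("CB-CG", "CG-CD1", "CG-CD2", "CD1-CE1", "CD2-CE2", "CE1-CZ",
          "CE2-CZ", "CZ-OH"),
  VAL = c("CB-CG1", "CB-CG2")
)

# side-chain hydrogen counts / geometry: "atom:nH:geom"
.SC_HYD <- list(
  ALA = c("CB:3:sp3"),
  ARG = c("CB:2:sp3", "CG:2:sp3", "CD:2:sp3", "NE:1:sp2", "CZ:0:sp2",
          "NH1:2:sp2", "NH2:2:sp2"),
  ASN = c("CB:2:sp3", "CG:0:sp2", "OD1:0:sp2", "ND2:2:sp2"),
  ASP = c("CB:2:sp3", "CG:0:sp2", "OD1:0:sp2", "OD2:0:sp2"),
  CYS = c("CB:2:sp3", "SG:1:sp3"),
  GLN = c("CB:2:sp3", "CG:2:sp3", "CD:0:sp2", "OE1:0:sp2", "NE2:2:sp2"),
  GLU = c("CB:2:sp3", "CG:2:sp3", "CD:0:sp2", "OE1:0:sp2", "OE2:0:sp2"),
  GLY = character(),
  HIS = c("CB:2:sp3", "CG:0:sp2", "ND1:0:sp2", "CD2:1:sp2", "CE1:1:sp2",
          "NE2:1:sp2"),
  ILE = c("CB:1:sp3", "CG1:2:sp3", "CG2:3:sp3", "CD1:3:sp3"),
  LEU = c("CB:2:sp3", "CG:1:sp3", "CD1:3:sp3", "CD2:3:sp3"),
  LYS = c("CB:2:sp3", "CG:2:sp3", "CD:2:sp3", "CE:2:sp3", "NZ:3:sp3"),
  MET = c("CB:2:sp3", "CG:2:sp3", "SD:0:sp3", "CE:3:sp3"),
  PHE = c("CB:2:sp3", "CG:0:sp2", "CD1:1:sp2", "CD2:1:sp2", "CE1:1:sp2",
          "CE2:1:sp2", "CZ:1:sp2"),
  PRO = c("CB:2:sp3", "CG:2:sp3", "CD:2:sp3"),
  SER = c("CB:2:sp3", "OG:1:sp3"),
  THR = c("CB:1:sp3", "OG1:1:sp3", "CG2:3:sp3"),
  TRP = c("CB:2:sp3", "CG:0:sp2", "CD1:1:sp2", "CD2:0:sp2", "NE1:1:sp2",
          "CE2:0:sp2", "CE3:1:sp2", "CZ3:1:sp2", "CH2:1:sp2", "CZ2:1:sp2"),
  TYR = c("CB:2:sp3", "CG:0:sp2", "CD1:1:sp2", "CD2:1:sp2", "CE1:1:sp2",
          "CE2:1:sp2", "CZ:0:sp2", "OH:1:sp3"),
  VAL = c("CB:1:sp3", "CG1:3:sp3", "CG2:3:sp3")
)

# formal side-chain charges at pH 7.4
.SC_CHARGE <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0,
                GLU = -1, GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = 1,
                MET = 0, PHE = 0, PRO = 0, SER = 0, THR = 0, TRP = 0,
                TYR = 0, VAL = 0)

parse_hyd <- function(strs) {
  if (length(strs) == 0) {
    return(tibble(atom = character(), nh = integer(), geom = character()))
  }
  parts <- strsplit(strs, ":", fixed = TRUE)
  tibble(
    atom = map_chr(parts, 1),
    nh = as.integer(map_chr(parts, 2)),
    geom = map_chr(parts, 3)
  )
}

parse_bonds <- function(strs) {
  if (length(strs) == 0) return(matrix(character(0), 0, 2))
  do.call(rbind, strsplit(strs, "-", fixed = TRUE))
}

#' Residue topology template
#'
#' Heavy-atom bond list, per-atom hydrogen counts and geometry, and the
#' formal side-chain charge for one of the 20 standard amino acids.
#' Histidine tautomers are selected with `his_state`: `"HIE"` (neutral,
#' proton on N-epsilon, the default), `"HID"` (neutral, proton on N-delta)
#' or `"HIP"` (doubly protonated, +1).
#'
#' @param resname three-letter residue code.
#' @param his_state histidine tautomer/charge state.
#' @return list with elements `bonds` (2-column character matrix),
#'   `hyd` (tibble: atom, nh, geom), `sc_charge` (numeric), and
#'   `heavy` (character vector of expected heavy atoms).
#' @export
res_topology <- function(resname, his_state = "HIE") {
  if (!resname %in% .AA3) {
    abort(paste0("no topology template for residue name '", resname, "'"),
          class = "mfcc_unparameterized_residue")
  }
  bb_bonds <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (!resname %in% c("GLY")) bb_bonds <- rbind(bb_bonds, c("CA", "CB"))
  bonds <- rbind(bb_bonds, parse_bonds(.SC_BONDS[[resname]]))

  n_nh <- if (resname == "PRO") 0L else 1L
  bb_hyd <- tibble(
    atom = c("N", "CA", "C", "O"),
    nh = c(n_nh, if (resname == "GLY") 2L else 1L, 0L, 0L),
    geom = c("sp2", "sp3", "sp2", "sp2")
  )
  hyd <- bind_rows(bb_hyd, parse_hyd(.SC_HYD[[resname]]))
  sc_charge <- unname(.SC_CHARGE[resname])

  if (resname == "HIS") {
    if (his_state == "HID") {
      hyd$nh[hyd$atom == "ND1"] <- 1L
      hyd$nh[hyd$atom == "NE2"] <- 0L
    } else if (his_state == "HIP") {
      hyd$nh[hyd$atom == "ND1"] <- 1L
      sc_charge <- 1
    } else if (his_state != "HIE") {
      abort(paste0("unknown histidine state '", his_state, "'"))
    }
  }
  list(bonds = bonds, hyd = hyd, sc_charge = sc_charge,
       heavy = unique(c(bonds)))
}

element_of <- function(atom_name) {
  # first alphabetic character of a (protein/water) PDB atom name
  core <- gsub("[^A-Za-z]", "", atom_name)
  toupper(substr(core, 1, 1))
}
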