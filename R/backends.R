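# Energy backends. The classical backend is a strictly pairwise-additive
# Coulomb + Lennard-Jones sum with a uniform dielectric dividing the
# Coulomb term -- a deliberately simple continuum screening model for
# desk-scale work. The QM route is an input-deck writer / log parser for an
# external Gaussian-style DFT engine; the package never runs the engine.

# per-element Lennard-Jones parameters (sigma in A, epsilon in kcal/mol)
.LJ_TABLE <- c(
  H = 2.50, C = 3.40, N = 3.25, O = 2.96, S = 3.56, P = 3.74, ZN = 1.95,
  F = 2.94, CL = 3.47, BR = 3.60, MG = 2.10, K = 3.30, NA. = 2.43, CA = 2.90
)
.LJ_EPS <- c(
  H = 0.030, C = 0.086, N = 0.170, O = 0.210, S = 0.250, P = 0.200,
  ZN = 0.250, F = 0.061, CL = 0.265, BR = 0.320, MG = 0.875, K = 0.100,
  NA. = 0.0874, CA = 0.450
)

lj_params <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  sigma <- unname(.LJ_TABLE[key])
  eps <- unname(.LJ_EPS[key])
  bad <- is.na(sigma)
  if (any(bad)) {
    abort(paste0("no Lennard-Jones parameters for element(s): ",
                 paste(unique(element[bad]), collapse = ", ")),
          class = "mfcc_parameterization_error")
  }
  list(sigma = sigma, eps = eps)
}

#' Classical pairwise backend specification
#'
#' @param dielectric uniform dielectric constant dividing the Coulomb term
#'   (the study conditions use 10 and 40).
#' @param lj include the Lennard-Jones term; set `FALSE` to evaluate the
#'   Coulomb part alone.
#' @return a `backend_spec` object.
#' @export
backend_classical <- function(dielectric = 40, lj = TRUE) {
  if (dielectric < 1) abort("dielectric must be >= 1")
  structure(list(kind = "classical_pairwise", dielectric = dielectric,
                 lj = lj),
            class = "backend_spec")
}

#' QM input-deck backend specification
#'
#' Describes single-point jobs for an external Gaussian-style engine:
#' functional, basis set, and a conductor-like polarizable continuum
#' (CPCM) solvent with the given dielectric.
#'
#' @param dielectric solvent dielectric written into the deck.
#' @param functional exchange-correlation functional label.
#' @param basis basis-set label.
#' @param solvent_model implicit-solvent keyword.
#' @return a `backend_spec` object.
#' @export
backend_qm_deck <- function(dielectric = 40, functional = "B97D",
                            basis = "6-311+G(d,p)", solvent_model = "CPCM") {
  if (dielectric < 1) abort("dielectric must be >= 1")
  structure(list(kind = "qm_deck", dielectric = dielectric,
                 functional = functional, basis = basis,
                 solvent_model = solvent_model),
            class = "backend_spec")
}

set_dielectric <- function(spec, dielectric) {
  spec$dielectric <- dielectric
  spec
}

#' Total classical energy of a fragment system
#'
#' Sums, over all unique atom pairs, the screened Coulomb term
#' `332.0637 q_a q_b / (eps d)` and (optionally) the Lennard-Jones term
#' `4 eps_ab ((sigma_ab/d)^12 - (sigma_ab/d)^6)` with Lorentz-Berthelot
#' combination. Strictly pairwise additive and deterministic; the arbitrary
#' energy zero cancels in the four-term fragment combination. Atoms flagged
#' as cut-bond saturation hydrogens carry zero charge and zero LJ well
#' depth (they are valence placeholders for the QM route).
#'
#' @param system a `fragment_system`, or any atom tibble with `element`,
#'   `x`, `y`, `z`, `charge` columns.
#' @param spec a classical `backend_spec` (see [backend_classical()]).
#' @return energy in kcal/mol.
#' @export
evaluate_classical <- function(system, spec = backend_classical()) {
  if (!identical(spec$kind, "classical_pairwise")) {
    abort("evaluate_classical needs a classical_pairwise backend spec")
  }
  n <- nrow(system)
  if (n < 2) return(0)
  if (anyNA(system$charge)) {
    abort(paste0("atoms without partial charges: ",
                 paste(head(system$atom[is.na(system$charge)], 5),
                       collapse = ", ")),
          class = "mfcc_parameterization_error")
  }
  lj <- lj_params(system$element)
  sat <- if ("sat_h" %in% names(system)) system$sat_h else rep(FALSE, n)
  q <- ifelse(sat, 0, system$charge)
  eps_i <- ifelse(sat, 0, lj$eps)
  sig_i <- lj$sigma

  d <- as.matrix(dist(as.matrix(system[, c("x", "y", "z")])))
  iu <- upper.tri(d)
  dv <- d[iu]
  if (any(dv < 0.5)) {
    warn(paste0(sum(dv < 0.5), " atom pair(s) closer than 0.5 A (clash); ",
                "energy returned anyway"))
  }
  qq <- (q %o% q)[iu]
  e <- sum(.KCOUL * qq / (spec$dielectric * dv))
  if (isTRUE(spec$lj)) {
    sig <- (outer(sig_i, sig_i, "+") / 2)[iu]
    epp <- sqrt(eps_i %o% eps_i)[iu]
    sr6 <- (sig / dv)^6
    e <- e + sum(4 * epp * (sr6^2 - sr6))
  }
  e
}

#' Write a Gaussian-style single-point input deck
#'
#' Emits a route line with the functional, basis and CPCM solvent keyword
#' (the dielectric is supplied through an `eps=` line in the trailing
#' input section), the charge/multiplicity line, and Cartesian coordinates.
#'
#' @param system a `fragment_system`.
#' @param spec a `qm_deck` backend spec (see [backend_qm_deck()]).
#' @param path output file path (conventionally `.gjf`).
#' @return `path`, invisibly.
#' @export
write_qm_deck <- function(system, spec, path) {
  if (!identical(spec$kind, "qm_deck")) {
    abort("write_qm_deck needs a qm_deck backend spec")
  }
  q <- attr(system, "net_charge")
  m <- attr(system, "multiplicity") %||% 1L
  if (is.null(q) || is.na(q) || abs(q - round(q)) > 1e-6) {
    abort("fragment system net charge must be a known integer",
          class = "mfcc_spec_error")
  }
  q <- as.integer(round(q))
  lines <- c(
    sprintf("%%chk=%s.chk", sub("\\.[^.]*$", "", basename(path))),
    sprintf("#P %s/%s SCRF=(%s,Read) SP", spec$functional, spec$basis,
            spec$solvent_model),
    "",
    sprintf("%s fragment single point", attr(system, "term") %||% "mfcc"),
    "",
    sprintf("%d %d", q, m),
    sprintf("%-2s %14.8f %14.8f %14.8f", system$element,
            system$x, system$y, system$z),
    "",
    sprintf("eps=%g", spec$dielectric),
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse the final SCF energy from a QM engine log
#'
#' Finds the last `SCF Done` energy (hartree) in the log text and converts
#' it to kcal/mol (1 hartree = 627.509474 kcal/mol). A non-converged SCF
#' marker raises a convergence error; a log without an energy line raises a
#' parse error.
#'
#' @param log_text character vector of log lines, or a single string.
#' @return energy in kcal/mol, with attribute `engine` when the log carries
#'   a program banner.
#' @export
parse_qm_energy <- function(log_text) {
  lines <- unlist(strsplit(log_text, "\n", fixed = TRUE))
  if (any(grepl("Convergence failure|SCF has not converged", lines))) {
    abort("SCF did not converge in the supplied log",
          class = "mfcc_convergence_error")
  }
  pat <- "SCF Done:[^=]*=\\s*([-+]?[0-9]*\\.?[0-9]+([DdEe][-+]?[0-9]+)?)"
  hits <- regmatches(lines, regexpr(pat, lines))
  if (length(hits) == 0) {
    abort("no SCF energy line found in log", class = "mfcc_parse_error")
  }
  val <- sub(pat, "\\1", hits[length(hits)])
  hartree <- as.numeric(gsub("[Dd]", "E", val))
  out <- hartree * .HARTREE_KCAL
  banner <- grep("Gaussian|ORCA|NWChem", lines, value = TRUE)
  if (length(banner) > 0) attr(out, "engine") <- trimws(banner[1])
  out
}
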