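# End-to-end orchestration: prep -> shells -> fragmentation -> evaluation
# -> decomposition -> reports, plus the harvest path that rebuilds the same
# reports from external QM logs. Classical and harvested-QM paths share all
# code downstream of energy evaluation.

default_config <- function() {
  list(
    input = NULL,          # PDB path (or supply `structure` directly)
    structure = NULL,      # prepared atom tibble (bypasses read/protonate)
    ligand = NULL,         # ligand resid; default: first ligand
    r_max = 10,
    dielectrics = c(10, 40),
    backend = "classical", # "classical" or "qm_deck"
    lj = TRUE,
    functional = "B97D",
    basis = "6-311+G(d,p)",
    solvent_model = "CPCM",
    hbond_dmax = 3.5,
    altloc = "highest_occupancy",
    atom_mode = "all_atoms",
    ph = 7.4,
    termini = "zwitterionic",
    region_map = NULL,     # path to a 2-column csv/tsv (atom, region)
    threshold = 0.10,
    out_dir = NULL,
    seed = 1
  )
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  if (is.null(cfg$input) && is.null(cfg$structure)) {
    abort("config needs `input` (PDB path) or `structure` (atom tibble)")
  }
  if (!cfg$backend %in% c("classical", "qm_deck")) {
    abort("backend must be 'classical' or 'qm_deck'")
  }
  if (is.null(cfg$out_dir)) abort("config needs `out_dir`")
  cfg
}

config_hash <- function(cfg) {
  rlang::hash(cfg[setdiff(names(cfg), c("out_dir", "structure"))])
}

stamp_line <- function(hash) {
  sprintf("# mfccpocket %s config_hash=%s",
          as.character(utils::packageVersion("mfccpocket")), hash)
}

write_stamped_csv <- function(df, path, hash) {
  writeLines(stamp_line(hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

records_for_export <- function(records) {
  records |>
    mutate(waters = map_chr(.data$waters, paste, collapse = ";"))
}

deck_name <- function(resid, term, eps) {
  sprintf("%s_%s_eps%g.gjf", gsub("[^A-Za-z0-9]", "-", resid), term, eps)
}

write_reports <- function(records, profile, structure, ligand_id, cfg,
                          hash, out) {
  write_stamped_csv(records_for_export(records),
                    file.path(out, "records.csv"), hash)
  jsonlite::write_json(
    list(stamp = stamp_line(hash),
         records = records_for_export(records)),
    file.path(out, "records.json"), auto_unbox = TRUE, digits = NA
  )
  prof_df <- as_tibble(profile)
  conv <- detect_convergence(profile, cfg$threshold)
  if (!is.data.frame(conv)) {
    conv <- tibble(dielectric = unique(prof_df$dielectric),
                   converged_radius = conv)
  }
  prof_df <- prof_df |>
    left_join(conv, by = "dielectric") |>
    mutate(converged = !is.na(.data$converged_radius) &
             .data$radius >= .data$converged_radius)
  write_stamped_csv(prof_df, file.path(out, "profile.csv"), hash)
  ranked <- rank_residues(records)
  write_stamped_csv(records_for_export(ranked),
                    file.path(out, "ranked.csv"), hash)
  totals <- records |>
    group_by(.data$dielectric) |>
    summarise(total_energy = sum(.data$energy), .groups = "drop") |>
    left_join(conv, by = "dielectric")
  jsonlite::write_json(
    list(stamp = stamp_line(hash), ligand = ligand_id,
         n_residues = length(unique(records$resid)), totals = totals),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out)
}

#' Run the full decomposition pipeline
#'
#' Validates the configuration, prepares the structure (PDB read +
#' protonation, unless a prepared atom tibble is supplied), and either
#' evaluates the classical per-residue decomposition and writes all
#' reports, or -- for the `qm_deck` backend -- writes the full tree of
#' single-point input decks (4 terms x pocket residues x dielectrics) plus
#' a manifest, awaiting external execution and [harvest_qm()].
#'
#' Outputs in `out_dir`: `config.yaml` (resolved configuration, package
#' version and config hash), `prepared.pdb`, and for classical runs
#' `records.csv/json`, `profile.csv`, `ranked.csv`, `summary.json`; for QM
#' runs `decks/` and `manifest.json`. Every report embeds the config hash.
#'
#' @param config named list or YAML file path; see Details for fields
#'   (`input`, `ligand`, `r_max`, `dielectrics`, `backend`, `hbond_dmax`,
#'   `altloc`, `atom_mode`, `region_map`, `threshold`, `out_dir`, `seed`).
#' @return an `mfcc_run` list: resolved config, output paths, and (for
#'   classical runs) the `mfcc_decomposition`.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)

  structure <- cfg$structure
  if (is.null(structure)) {
    structure <- read_pdb(cfg$input, altloc_policy = cfg$altloc)
    structure <- assign_protonation(structure, ph = cfg$ph,
                                    termini = cfg$termini)
  }
  rt <- residue_table(structure)
  ligand_id <- cfg$ligand %||% rt$resid[rt$role == "ligand"][1]
  if (is.na(ligand_id)) abort("no ligand residue in input structure")

  region_map <- NULL
  if (!is.null(cfg$region_map)) {
    region_map <- readr::read_csv(cfg$region_map, show_col_types = FALSE)
  }

  write_pdb(structure, file.path(out, "prepared.pdb"))
  cfg_out <- cfg[setdiff(names(cfg), "structure")]
  cfg_out$config_hash <- hash
  cfg_out$version <- as.character(utils::packageVersion("mfccpocket"))
  yaml::write_yaml(cfg_out, file.path(out, "config.yaml"))

  if (cfg$backend == "classical") {
    dec <- decompose_pocket(
      structure, ligand_id, r_max = cfg$r_max,
      dielectrics = cfg$dielectrics,
      backend = backend_classical(lj = cfg$lj),
      hbond_dmax = cfg$hbond_dmax, atom_mode = cfg$atom_mode,
      region_map = region_map, threshold = cfg$threshold
    )
    write_reports(tidy(dec), dec$profile, structure, ligand_id, cfg, hash,
                  out)
    res <- structure(list(config = cfg_out, out_dir = out,
                          decomposition = dec), class = "mfcc_run")
    return(invisible(res))
  }

  # qm_deck: emit the deck tree + manifest
  deck_dir <- file.path(out, "decks")
  dir.create(deck_dir, showWarnings = FALSE)
  pocket <- select_shell(structure, ligand_id, cfg$r_max,
                         atom_mode = cfg$atom_mode)
  wmap <- assign_waters(structure, pocket, cfg$hbond_dmax)
  entries <- list()
  for (id in pocket) {
    w <- wmap$water[!is.na(wmap$residue) & wmap$residue == id]
    capped <- build_caps(structure, id, waters = w)
    systems <- build_fragment_systems(capped, ligand_id, structure)
    for (eps in cfg$dielectrics) {
      spec <- backend_qm_deck(dielectric = eps, functional = cfg$functional,
                              basis = cfg$basis,
                              solvent_model = cfg$solvent_model)
      for (term in names(systems)) {
        f <- deck_name(id, term, eps)
        write_qm_deck(systems[[term]], spec, file.path(deck_dir, f))
        entries[[length(entries) + 1]] <- list(
          resid = id, term = term, dielectric = eps, deck = f,
          net_charge = attr(systems[[term]], "net_charge"),
          waters = as.list(w)
        )
      }
    }
  }
  manifest <- list(stamp = stamp_line(hash), ligand = ligand_id,
                   r_max = cfg$r_max, threshold = cfg$threshold,
                   atom_mode = cfg$atom_mode, entries = entries)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(config = cfg_out, out_dir = out,
                           n_decks = length(entries)), class = "mfcc_run"))
}

#' Harvest external QM logs into per-residue records
#'
#' Matches every deck in a `qm_deck` run's manifest with a log file
#' (`<deck>.log` in `logs_dir`), parses the final SCF energies, applies the
#' four-term combination per residue and dielectric, and regenerates the
#' same reports the classical path writes. Residues with missing or failed
#' logs are flagged and skipped; the harvest is partial rather than fatal.
#'
#' @param run_dir output directory of a `qm_deck` [run_pipeline()] run.
#' @param logs_dir directory containing the engine logs.
#' @return list with `records` (per-residue tibble), `gaps` (tibble of
#'   skipped residues and reasons), and the output directory.
#' @export
harvest_qm <- function(run_dir, logs_dir) {
  mpath <- file.path(run_dir, "manifest.json")
  if (!file.exists(mpath)) abort(paste0("no manifest.json in ", run_dir))
  manifest <- jsonlite::read_json(mpath)
  structure <- read_pdb(file.path(run_dir, "prepared.pdb"))
  cfg <- yaml::read_yaml(file.path(run_dir, "config.yaml"))
  hash <- cfg$config_hash

  ent <- map(manifest$entries, function(e) {
    tibble(resid = e$resid, term = e$term, dielectric = e$dielectric,
           deck = e$deck,
           waters = list(unlist(e$waters) %||% character()))
  }) |> list_rbind()

  ent$energy <- NA_real_
  ent$status <- "ok"
  for (i in seq_len(nrow(ent))) {
    lf <- file.path(logs_dir, sub("\\.gjf$", ".log", ent$deck[i]))
    if (!file.exists(lf)) {
      ent$status[i] <- "missing log"
      next
    }
    e <- tryCatch(parse_qm_energy(readLines(lf, warn = FALSE)),
                  error = function(err) conditionMessage(err))
    if (is.character(e)) {
      ent$status[i] <- e
    } else {
      ent$energy[i] <- as.numeric(e)
    }
  }

  by_re <- ent |> group_by(.data$resid, .data$dielectric)
  combined <- by_re |>
    group_modify(function(d, key) {
      if (any(d$status != "ok") || nrow(d) != 4) {
        bad <- paste(unique(d$status[d$status != "ok"]), collapse = "; ")
        return(tibble(energy = NA_real_,
                      status = if (bad == "") "incomplete terms" else bad,
                      waters = list(d$waters[[1]])))
      }
      es <- setNames(d$energy, d$term)
      tibble(energy = combine_mfcc_terms(es["L_CRC"], es["L_CC"],
                                         es["CRC"], es["CC"]),
             status = "ok", waters = list(d$waters[[1]]))
    }) |>
    ungroup()

  gaps <- combined |> filter(.data$status != "ok") |>
    select("resid", "dielectric", "status")
  records <- combined |> filter(.data$status == "ok")

  rt <- residue_table(structure)
  meta <- rt[match(records$resid, rt$resid), c("chain", "resno", "resname")]
  records <- bind_cols(records[, "resid"], meta,
                       records[, c("energy", "dielectric", "waters")])
  ann <- records |>
    distinct(.data$resid) |>
    group_by(.data$resid) |>
    group_modify(function(d, key) {
      r <- annotate_contact(tibble(resid = key$resid), structure,
                            manifest$ligand)
      r[, c("min_distance", "nearest_ligand_atom", "contact_region")]
    }) |>
    ungroup()
  records <- records |> left_join(ann, by = "resid")

  if (nrow(records) > 0 && nrow(gaps) == 0) {
    profile <- shell_sweep(records, structure, manifest$ligand,
                           r_max = manifest$r_max,
                           atom_mode = manifest$atom_mode,
                           threshold = manifest$threshold)
    write_reports(records, profile, structure, manifest$ligand,
                  list(threshold = manifest$threshold), hash, run_dir)
  } else if (nrow(records) > 0) {
    # partial harvest: per-residue records only (the shell profile needs a
    # complete pocket)
    write_stamped_csv(records_for_export(records),
                      file.path(run_dir, "records.csv"), hash)
  }
  if (nrow(gaps) > 0) {
    write_stamped_csv(gaps, file.path(run_dir, "gaps.csv"), hash)
  }
  list(records = records, gaps = gaps, out_dir = run_dir)
}

#' Export the classical parameterization of a structure
#'
#' Writes the per-atom parameter table (residue, atom name, partial charge,
#' Lennard-Jones sigma and epsilon) used by the classical backend.
#'
#' @param structure atom tibble with charges.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_parameters <- function(structure, path) {
  lj <- lj_params(structure$element)
  df <- tibble(residue = structure$resid, resname = structure$resname,
               atom_name = structure$atom, charge = structure$charge,
               sigma = lj$sigma, epsilon = ifelse(structure$sat_h, 0,
                                                  lj$eps))
  readr::write_tsv(df, path)
  invisible(path)
}
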