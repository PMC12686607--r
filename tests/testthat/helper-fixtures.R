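# shared fixtures, built in code and memoised per test session

.fixture_env <- new.env(parent = emptyenv())

toy_fixture <- function(key = "default", ...) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_toy_complex(toy_spec(...))
  }
  .fixture_env[[key]]
}

toy_ligand_id <- "L:1:"

# fixed-width PDB coordinate line for hand-crafted parser fixtures
pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, elem = NULL, rec = "ATOM") {
  if (is.null(elem)) elem <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# independent brute-force shell selection: plain double loop over atoms
brute_shell <- function(structure, ligand_id, r) {
  lig <- structure[structure$resid == ligand_id, ]
  prot <- structure[structure$role == "protein", ]
  hits <- character()
  for (id in unique(prot$resid)) {
    res <- prot[prot$resid == id, ]
    found <- FALSE
    for (i in seq_len(nrow(res))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((res$x[i] - lig$x[j])^2 + (res$y[i] - lig$y[j])^2 +
                    (res$z[i] - lig$z[j])^2)
        if (d <= r) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) hits <- c(hits, id)
  }
  hits
}

# brute-force nearest-qualifying water assignment
brute_water_assign <- function(structure, pocket, dmax) {
  waters <- unique(structure$resid[structure$role == "water"])
  out <- list()
  for (w in waters) {
    o <- structure[structure$resid == w & structure$element == "O", ][1, ]
    best <- NA_character_
    bestd <- Inf
    for (id in pocket) {
      res <- structure[structure$resid == id &
                         structure$element %in% c("N", "O", "S"), ]
      for (i in seq_len(nrow(res))) {
        d <- sqrt((res$x[i] - o$x)^2 + (res$y[i] - o$y)^2 +
                    (res$z[i] - o$z)^2)
        if (d <= dmax && d < bestd) {
          bestd <- d
          best <- id
        }
      }
    }
    out[[w]] <- best
  }
  out
}
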