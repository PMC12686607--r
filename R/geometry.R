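# Small 3-vector toolbox shared by the peptide builder, the hydrogen placer
# and the cap-saturation code. All coordinates are in Angstrom, all angles in
# degrees at the interfaces (radians internally).

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180

# Natural-extension reference frame (NeRF) placement: returns the position of
# an atom D bonded to c, with bond length |D-c|, angle D-c-b and proper
# torsion D-c-b-a.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Rodrigues rotation of row-matrix xyz about unit axis by angle (degrees).
rotate_about <- function(xyz, axis, angle) {
  k <- unitv(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz %*% t(R)
}

# Standard X-H bond lengths by heavy-atom element.
h_bond_length <- function(element) {
  switch(element, N = 1.01, O = 0.96, S = 1.34, C = 1.09, 1.00)
}

# Complete the coordination sphere of heavy atom `x` with `n_new` hydrogens.
#
# `nbrs` is a matrix (one row per known bonded neighbour position), `geom` is
# "sp3" or "sp2", and `ref` is a reference position (a neighbour of the first
# neighbour) needed when only one neighbour is known, to fix the torsion.
# Returns a matrix of hydrogen positions (n_new x 3). Deterministic.
complete_positions <- function(x, nbrs, n_new, geom = "sp3", ref = NULL,
                               blen = 1.09) {
  if (n_new == 0) return(matrix(numeric(0), 0, 3))
  k <- if (is.null(nbrs)) 0L else nrow(nbrs)

  if (k == 0) {
    # free atom (water oxygen): fixed canonical orientation
    if (n_new == 1) return(matrix(x + c(blen, 0, 0), 1, 3))
    ang <- deg2rad(104.52)
    return(rbind(x + blen * c(1, 0, 0),
                 x + blen * c(cos(ang), sin(ang), 0)))
  }

  units <- t(apply(nbrs, 1, function(p) unitv(p - x)))

  if (k >= 3) {
    dir <- -colSums(units)
    return(matrix(x + blen * unitv(dir), 1, 3))
  }

  if (k == 2) {
    bis <- -(units[1, ] + units[2, ])
    if (vnorm(bis) < 1e-8) {
      # collinear neighbours: pick any perpendicular
      bis <- vcross(units[1, ], c(0, 0, 1))
      if (vnorm(bis) < 1e-8) bis <- vcross(units[1, ], c(0, 1, 0))
    }
    bis <- unitv(bis)
    if (n_new == 1) return(matrix(x + blen * bis, 1, 3))
    perp <- unitv(vcross(units[1, ], units[2, ]))
    half <- deg2rad(109.47 / 2)
    return(rbind(x + blen * (cos(half) * bis + sin(half) * perp),
                 x + blen * (cos(half) * bis - sin(half) * perp)))
  }

  # k == 1: torsion fixed by `ref`
  if (is.null(ref)) abort("hydrogen placement with one neighbour needs a reference atom")
  ang <- if (identical(geom, "sp2")) 120 else 109.47
  tors <- if (identical(geom, "sp2")) {
    c(0, 180)
  } else {
    c(180, 60, -60)
  }
  tors <- tors[seq_len(n_new)]
  out <- t(vapply(tors, function(tt) {
    place_atom(ref, nbrs[1, ], x, blen, ang, tt)
  }, numeric(3)))
  out
}
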