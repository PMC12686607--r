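---
title: "Per-residue interaction energies with conjugated caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue interaction energies with conjugated caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mfccpocket)
```

## The model

Given a prepared (hydrogen-complete, charged) protein–ligand complex,
`mfccpocket` estimates how much each binding-pocket residue contributes to
the binding energy. The protein is fragmented residue by residue using the
molecular fractionation with conjugated caps (MFCC) scheme. For residue
$R_i$, the two covalently adjacent residues $C_{i-1}$ and $C_{i+1}$ are
carried along as *caps* that preserve the local chemical environment of
the peptide bonds; cut bonds at the outer edges of the caps are saturated
with hydrogens so no fragment has dangling valences. Four fragment systems
are evaluated and combined:

$$E(L\!-\!R_i) \;=\; E(L\,C_{i-1}R_iC_{i+1}) \;-\; E(L\,C_{i-1}C_{i+1})
\;-\; E(C_{i-1}R_iC_{i+1}) \;+\; E(C_{i-1}C_{i+1})$$

where $L$ is the ligand. Subtracting the ligand–caps and caps-only terms
removes everything the caps contribute, leaving the ligand–residue
interaction. Negative energies are attractive, positive repulsive.
Crystallographic waters are attached to the residue with which they form
the closest hydrogen bond and travel with that residue through the four
terms, so water-mediated contacts are credited to the right residue.

Pocket residues are selected on a grid of nested spheres of radius
$r = n/2$ Å around the ligand. The cumulative total binding energy is
tracked as $r$ grows, and the pocket is considered converged at the first
radius where the next shell changes the total by less than 10 %
(relative). The analysis is normally carried to $r = 10$ Å regardless, so
slowly decaying contributions are still collected.

## Energy backends

Two backends share one contract (a total energy per fragment system):

* **Classical pairwise** (`backend_classical()`): the sum over unique atom
  pairs of a screened Coulomb term $332.0637\,q_a q_b/(\varepsilon d)$
  (kcal/mol, charges in elementary units, $d$ in Å) plus a
  Lennard-Jones term with Lorentz–Berthelot combination. The uniform
  dielectric $\varepsilon$ dividing the Coulomb term is a deliberately
  simple continuum-screening stand-in; it makes the backend strictly
  pairwise additive, which is what lets the fragment combination be
  checked *exactly* against a direct supermolecule sum. The arbitrary
  energy zero of a fragment cancels in the four-term combination.
* **QM deck writer** (`backend_qm_deck()`): the fidelity path. It writes
  Gaussian-style single-point input decks (default route
  B97D/6-311+G(d,p) with a CPCM continuum at the requested dielectric)
  for all four systems of every pocket residue, and `harvest_qm()` parses
  the resulting logs (last SCF energy, 1 hartree = 627.509474 kcal/mol)
  and applies the same four-term combination. The package never runs the
  engine.

Dielectric constants 10 and 40 are evaluated by default, and rankings are
reported at $\varepsilon = 40$; both choices follow common practice for
continuum treatments of protein–ligand interfaces, where values around 40
have repeatedly given the best agreement with experiment.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `r_max` | 10 | Å | outer pocket radius (shell grid 0.5, 1.0, …) |
| `dielectrics` | 10, 40 | – | Coulomb screening / CPCM `eps` |
| `threshold` | 0.10 | fraction | shell-stability rule |
| `hbond_dmax` | 3.5 | Å | water donor–acceptor heavy-atom cutoff |
| saturation N–H / C–H | 1.01 / 1.09 | Å | cut-bond capping hydrogens |
| `altloc` | highest occupancy | – | alternate-location resolution |
| `atom_mode` | all atoms | – | shell distance criterion |

The hydrogen-bond criterion for waters is distance-only (no angle term):
it keeps the assignment reproducible, and the cutoff is a configuration
knob. Ties between residues are broken by pocket order; ties between
equidistant ligand atoms in contact annotation by the lower atom index.

## Numerical and design choices

* **Cap extent.** Caps are *entire* adjacent residues, not just the
  backbone unit, matching the definition of the conjugated cap as the
  covalently bonded neighbour along the chain. Chain termini yield
  single-sided caps that retain their real terminal groups.
* **Cap-saturation hydrogens are null atoms classically.** The hydrogens
  that saturate cut bonds carry zero partial charge and zero LJ well
  depth in the classical backend. They are valence placeholders needed by
  the QM route; nulling them makes the cap cancellation algebraically
  exact for any pairwise-additive potential, which is the property the
  oracle tests assert at 1e-8 kcal/mol. QM backends treat them as real
  hydrogens.
* **Convergence ratio denominator.** The stability rule uses
  $|E_{k+1}-E_k|/|E_{k+1}|$ (the newer total). The alternative
  (the older total) differs negligibly near convergence; the convention
  is recorded on every profile object.
* **Charge model.** Backbone atoms take fixed amide-unit charges;
  side-chain atoms follow simple element/valence rules; each residue is
  then renormalized uniformly so its partial charges sum *exactly* to its
  formal charge (pH 7.4 rules: ASP/GLU −1, LYS/ARG +1, HIS neutral
  Nε tautomer unless overridden, termini zwitterionic). This minimal
  parameterization is deliberately simple — it exists to exercise the
  fragment algebra at desk scale, not to predict absolute energetics.
* **Degenerate inputs.** Single-atom systems evaluate to zero (no pairs);
  non-bonded contacts closer than 0.5 Å warn but still evaluate; an empty
  pocket returns an empty record table and a zero profile; per-residue
  failures are collected and only abort a run when more than 10 % of the
  pocket fails.
* **Metal ions** are retained in the structure with their nominal charges
  but excluded from the residue decomposition (they have no caps).

## What the synthetic generator emulates

`make_toy_complex()` builds an extended-conformation peptide with
idealized geometry and template side chains, protonated and charged by
the same code path real structures go through. A rigid 12-atom
quinone-like ligand is placed at a chosen distance from the middle
residue, approached perpendicular to the chain axis and in a random rigid
orientation; waters are placed at hydrogen-bond range (2.7–3.3 Å) of
selected backbone carbonyls, scanning directions around the carbonyl axis
so they never clash with side chains. Gaussian jitter (default 0.05 Å)
perturbs the peptide atoms; the ligand is kept rigid so its exact
inversion symmetry — net charge zero and zero dipole — is preserved.
That symmetry matters for the separation-limit checks: the slowest
surviving multipole term against a charged residue is charge–quadrupole
($\sim 1/r^3$), which at 50 Å is below $10^{-3}$ kcal/mol at the default
reporting dielectric ($\varepsilon = 40$) and around $10^{-3}$ at
$\varepsilon = 10$; the exact $1/\varepsilon$ Coulomb scaling connects
the two.

What the toy complexes do **not** emulate: crystallographic side-chain
rotamer diversity, realistic force-field charges, polarization, or any
quantum effect. Passing the desk-scale suite therefore demonstrates that
the fragment bookkeeping, water attachment, shell accounting and
combination algebra are correct — it says nothing about the accuracy of
the classical potential on real complexes, for which the QM deck route
exists.

## A short run

```{r example}
s <- make_toy_complex(toy_spec(n_residues = 7, seed = 1))
dec <- decompose_pocket(s, r_max = 10, region_map = toy_ligand_regions())
glance(dec)
rank_residues(dec)[, c("resid", "resname", "energy", "classification")]
```

```{r plots, fig.width = 6, fig.height = 3}
autoplot(dec$profile)
```

Validation problem sizes: the oracle-equivalence suite runs 100 seeded
5-residue complexes (≈500 residue evaluations); additivity, shell and
separation checks use 5–7-residue complexes with 0–3 waters. These sizes
exercise every branch (charge states −1/0/+1, single caps at termini,
attached waters) while keeping the whole suite fast.

## Known limitations

* Protonation is rule-based at pH 7.4; no pKa prediction. Unusual
  residues require the caller to supply charges or a rebuild hook.
* The classical backend's absolute energies are not comparable to DFT
  results; only the *decomposition structure* transfers.
* Disulfide bridges are not cut specially; covalent ligands are out of
  scope.
* The toy generator builds 12 of the 20 residue types (all 20 are
  supported when reading real structures).
* Basis-set and counterpoise handling beyond label pass-through in the
  deck writer is out of scope; no BSSE correction is applied to the four
  terms.
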