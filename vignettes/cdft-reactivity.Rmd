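---
title: "Conceptual-DFT reactivity descriptors for peptides: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conceptual-DFT reactivity descriptors for peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftkit)
```

## The problem this package addresses

Bioactive peptides — here the virotoxins, monocyclic toxic heptapeptides
of *Amanita virosa* — are candidates for drug repurposing, but their
chemical reactivity and solubility-relevant properties (such as pKa) are
rarely measured. Conceptual density functional theory (CDFT) derives
reactivity descriptors from quantities a routine quantum-chemistry (QC)
calculation already produces. `cdftkit` takes that QC output — frontier
orbital energies, Mulliken population tables for three charge states, and
cube-format electron densities — and computes the descriptor set, so the
expensive electronic-structure step stays outside the package.

## The model

### Koopmans-in-DFT (KID) energies

Within DFT, Koopmans' theorem is only approximately valid, but for
well-behaved functionals the vertical ionization potential and electron
affinity can be identified with the frontier eigenvalues:

$$ I = -\varepsilon_{\mathrm{HOMO}}, \qquad A = -\varepsilon_{\mathrm{LUMO}}. $$

This avoids separate cation/anion SCF calculations, which for peptides of
this size are costly and convergence-prone. `kid_deviation()` quantifies
how good the identification is when $\Delta$SCF total energies *are*
available: $J_I = |\varepsilon_H + I_{\Delta SCF}|$ and
$J_A = |\varepsilon_L + A_{\Delta SCF}|$. Composite well-behavedness
indices built from these in other work are not defined here and are out
of scope.

### Global descriptors

From $I$ and $A$ (eV):

| descriptor | formula | meaning |
|---|---|---|
| electronegativity $\chi$ | $(I+A)/2$ | tendency to attract electrons |
| global hardness $\eta$ | $I-A$ | resistance of the density to deformation (= HOMO–LUMO gap here) |
| electrophilicity $\omega$ | $\chi^2/2\eta$ | stabilization on acquiring electrons |
| electrodonating power $\omega^-$ | $(3I+A)^2/16\eta$ | propensity to donate charge |
| electroaccepting power $\omega^+$ | $(I+3A)^2/16\eta$ | propensity to accept charge |
| net electrophilicity $\Delta\omega^\pm$ | $\omega^- + \omega^+$ | combined donor/acceptor character |

Two identities follow algebraically and are enforced by property tests:
$\omega^- - \omega^+ = \chi$ and $\Delta\omega^\pm = \omega^- + \omega^+$.
The convention $\eta = I - A$ (not $(I-A)/2$) is fixed by the reference
data, where the hardness column equals the gap column exactly.

The maximum absorption wavelength uses the gap as a proxy for the lowest
excitation energy, $\lambda_{max} = hc/\eta$ with
$hc = 1239.84193$ eV nm, reported at integer nm. The pKa uses a linear
QSAR in hardness calibrated on small peptides,
$\mathrm{p}K_a = 16.3088 - 0.8268\,\eta$, reported at 2 decimals; both
coefficient sets are overridable (`pka_model()`, config file) because
they are calibrations, not physics.

### Local descriptors

Condensed Fukui functions come from Mulliken charges $q_k$ of the
$N$, $N{-}1$, $N{+}1$ electron systems at the neutral geometry:

$$ f_k^- = q_k(N{-}1) - q_k(N), \qquad f_k^+ = q_k(N) - q_k(N{+}1), $$

each summing to 1 for one-electron differences. The condensed dual
descriptor $\Delta f_k = f_k^+ - f_k^-$ is positive where nucleophilic
attack is preferred and negative where electrophilic attack is preferred;
reports scale it by 100 (display only — stored values are never scaled).
Parr functions are the Mulliken atomic spin densities of the radical
anion ($P_k^+$) and radical cation ($P_k^-$), taken raw: no
renormalization, because published tables need not sum to a round number
after truncation. Deviations of a spin-density column from the
unpaired-electron count beyond 0.01 warn rather than error. Volumetric
Fukui functions are pointwise density differences on congruent cube
grids, with the grid-quadrature integral reported as a quality check
(≈ 1 for well-resolved grids).

Hydrogens are kept as distinct atoms throughout: the reference site
labels ("50 C", "24 N") index raw per-atom tables, so summing hydrogens
into heavy atoms would break traceability.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| eV per Hartree | 27.211386245988 | eV | CODATA 2018; sources rarely state their constant, and 3-dp reporting absorbs the difference |
| $hc$ | 1239.84193 | eV nm | standard photon energy–wavelength product; integer-nm rounding absorbs constant choice |
| pKa intercept / slope | 16.3088 / −0.8268 | — / eV$^{-1}$ | peptide QSAR calibration; override for other molecule classes |
| charge-sum tolerance | 1e-3 | e | printed Mulliken tables carry 5–6 decimals; looser would hide misaligned inputs |
| spin-sum tolerance | 1e-2 | e | spin contamination legitimately moves Mulliken spin sums at this scale |
| grid congruence tolerance | 1e-6 | Bohr | cube headers print 6 decimals |

## Numerical choices

* **Rounding for reports.** Descriptors print at 3 decimals, pKa at 2,
  wavelengths at integer nm, using IEEE round-half-to-even. Half-even was
  chosen over half-away-from-zero because the two exact decimal midpoints
  arising in the reference set (χ = 3.4545 and 3.7405) reproduce the
  published cells only under half-even. Stored values are never rounded.
* **Reproduction limits.** The reference descriptor table was computed
  from unrounded orbital energies; recomputing from the 3-dp printed
  energies reproduces 24 of its 30 cells exactly and the rest to within
  0.0011 eV. This is an information-theoretic floor, not a bug: the
  ±0.0005 eV quantization of printed inputs propagates to ~±0.002 eV in
  the quadratic descriptors. The acceptance test asserts the strict claim
  and is expected to stay red on those six cells.
* **Degenerate inputs.** A non-positive gap ($I \le A$) is an error
  everywhere (hardness would vanish or flip sign). An all-zero dual
  column ranks both extreme sites at atom 1 by the deterministic
  lowest-index tie-break and flags the result degenerate.
* **Last-block rule.** Optimization logs print orbital listings and
  Mulliken blocks at every step; parsers use only the final block.
  Unrestricted listings take the HOMO as the maximum over both spin
  channels' occupied sets and the LUMO as the minimum over both virtual
  sets.

## What the synthetic generator emulates — and what it does not

`mock_spec()` + `make_mock_log()` emit Gaussian-style logs whose parsed
HOMO/LUMO hit requested targets (to the 1e-5 Hartree print precision) and
whose Mulliken columns sum *exactly* to each state's net charge and
unpaired-electron count — exactness of the closure sums is prioritized
over realism, since that is what the conservation invariants test.
Charges are drawn from a symmetric distribution and shifted; real charge
distributions are structured by chemistry, and real spin densities
localize on few atoms. `make_mock_cubes()` builds densities as sums of
isotropic Gaussians (σ = 1.2 Bohr, 20³ points over a 12-Bohr box) so that
density differences integrate to one electron analytically; real
densities have nuclear cusps and exponential tails that stress grid
quadrature harder. A green conservation or integral test therefore
establishes the *bookkeeping* (alignment, signs, normalization, parser
closure), not the quality of any population analysis. Generation is
seed-deterministic to the byte.

The bundled virotoxin fixtures are printed reference values, not
recomputed ones; tests against them establish agreement with the
published tables, within the reproduction limits above.

## Known limitations

* One log dialect (Gaussian-style text) plus JSON records; no wavefunction
  or basis-set parsing; the MO-cube dialect (negative atom count) is
  rejected rather than interpreted.
* Mulliken is the only population scheme wired in; Hirshfeld/NPA would
  enter through `population_table()` as a seam but no parser exists.
* The pKa line is evaluation-only; fitting it is out of scope, and its
  validity outside peptides of comparable size is unknown.
* The gap proxy for $\lambda_{max}$ ignores excitonic and orbital-overlap
  effects a TD-DFT calculation would capture.

## A worked example

```{r example}
bundle <- load_virotoxin_fixtures()
report <- run_global(bundle$records)
report$rows
```

Local descriptors from synthetic inputs:

```{r local}
logs <- make_mock_log(mock_spec(seed = 7, n_atoms = 10))
run_local(logs$neutral, logs$cation, logs$anion)
```
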