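---
title: "Methods: the impedance network protein analogue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the impedance network protein analogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inpa)
```

## The model

`inpa` treats a protein as an electrical network derived from its tertiary
structure. Amino acids are single interacting centres located at their Cα
atoms; every pair closer than an interaction radius $R_C$ is joined by a
link. A link of length $l_{ij}$ carries the cross-sectional area between
the two interaction spheres, $A_{ij} = \pi (R_C^2 - l_{ij}^2/4)$, and the
elemental impedance of a resistor in parallel with a capacitor,

$$Z_{ij}(\omega) = \frac{l_{ij}}{A_{ij}}
  \frac{1}{\rho^{-1} + i\,\varepsilon_{ij}\varepsilon_0\,\omega}.$$

The resistivity $\rho$ is the same for every link (default
$10^{10}\ \Omega\,$m, an indicative protein value; the model is agnostic
about the microscopic conduction mechanism behind it), and
$\varepsilon_{ij}$ combines the relative dielectric constants of the two
residues. With ideal contacts on chosen node sets, Kirchhoff's equations
give the two-terminal impedance $Z(\omega)$, evaluated over a log-spaced
frequency grid (default 0.1 Hz to $10^5$ Hz) and summarized as a Nyquist
plot. The static response is the linear law $V = Z(0) I$.

The key modelling assumption is that structure determines electrical
response: a conformational change rearranges the link set and therefore
shifts $Z(\omega)$ and the I-V curve. The *relative* change between
conformers, not the absolute impedance, is the intended observable.

Nonlinearity enters through stochastic sequential tunneling. Each link can
occupy a high-resistivity state ($\rho$) or a low-resistivity state
($\rho_{\mathrm{low}}$). Given the self-consistent potential drop
$V_{ij}$ across the link, the activation probability is the WKB
transmission through a barrier of height $\Phi$:

* direct regime, $eV_{ij} \le \Phi$:
  $P_{ij} = \exp\!\big(-\tfrac{2 l_{ij}}{\hbar}\sqrt{2m(\Phi - eV_{ij})}\big)$,
  reaching $P = 1$ when the drop equals the barrier;
* injection (Fowler–Nordheim) regime, $eV_{ij} > \Phi$: the barrier tilts
  into a triangle and
  $P_{ij} = \exp\!\big(-\tfrac{4 l_{ij}\sqrt{2m}\,\Phi^{3/2}}{3\hbar e V_{ij}}\big)$.

The network is solved at $\omega = 0$, every link's state is redrawn
synchronously from $P_{ij}$, and the loop repeats; after a burn-in the
terminal current is averaged, then means and standard deviations are taken
across Monte-Carlo realizations. Because activated links short out and
concentrate the remaining voltage on high-resistivity links, activation is
self-reinforcing and the I-V is superlinear — the mechanism that the
linear law cannot produce.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| $R_C$ | Å | user-set | Must exceed the ~3.8 Å backbone spacing or the chain disconnects and the impedance tends to infinity. Working values of a few to tens of Å; past the structure's diameter the graph is complete and no longer descriptive. |
| $\rho$ | Ω·m | $10^{10}$ | Sets the global impedance scale; a pure prefactor of $Z(0)$. |
| $\varepsilon$ per residue | – | 4 (flat table) | Editable two-column text file; pairwise combination arithmetic (default) or geometric mean. Residue-specific polarizabilities can be supplied but are not invented here. |
| $\Phi$ (`phi_mean`) | eV | 0.069 | Reference barrier values: single barrier 0.053 or 0.059; Gaussian mean 0.069. |
| `phi_sigma` | eV | 0.044 | Gaussian spread of quenched per-link barriers; 0 switches the Gaussian machinery off with no RNG consumption. |
| `m_eff` | kg | bare electron mass | Length-independent. |
| $\rho_{\mathrm{low}}$ | Ω·m | $10^{-6}\rho$ | The low-state resistivity is a model knob: only its being far below $\rho$ matters qualitatively. Equality with $\rho$ is allowed and makes state changes electrically invisible (an exact linear-limit check). |
| `leakage_R` | Ω | none | Global resistor in parallel with the whole network, emulating conduction through contact regions (trimers, lipids) that dominates at low bias. |
| burn-in | – | 20% of `max_iter` (default 200) | Iterations discarded before averaging. |

Frequency grids use 10 points per decade by default (standard impedance-
spectroscopy practice); the range is fully configurable (spectroscopy
comparisons may extend to 1 mHz–100 kHz).

## Contacts

Contacts are ideal: each contact set is merged into one equipotential
supernode with zero internal impedance, the output supernode is grounded,
and unit current is injected at the input. Point contacts default to the
first and last residue. Planar contacts take every node within a depth of
the extreme projection along an axis; the default axis is the structure's
principal axis of inertia (the physical membrane normal of an AFM
experiment is not defined by the structure alone, so it is overridable).
Depth 0 reduces exactly to the extreme node(s). Shorting more nodes can
only decrease $Z(0)$, and fewer residues in series means larger per-link
drops — hence higher currents and a lower direct-to-injection crossover
voltage at deeper indentation.

## Synthetic structures

Downloaded structures are not required anywhere: `make_helix()` builds an
ideal α-helical Cα trace (rise 1.5 Å, radius 2.3 Å, twist 100°, giving the
3.83 Å consecutive spacing of real backbones), and `make_conformer_pair()`
derives an "activated" conformer by a rigid hinge rotation of the
C-terminal half (angle calibrated so the RMS displacement of the moved
half equals the requested value) or by Gaussian coordinate noise with a
chosen per-atom RMS. These emulate what the pipeline needs from a real
pair of deposited conformers — an ordered compact Cα chain and a
controlled structural perturbation — and nothing more. They do **not**
reproduce real features such as side-chain packing, chain breaks, loop
heterogeneity, multimeric contacts or residue-specific dielectric
environments, so passing tests demonstrate correctness of the machinery,
not biological accuracy for any particular receptor. Real structures enter
through `read_calpha_pdb()` (wwPDB ATOM records via bio3d: Cα only,
highest-occupancy altloc, all chains of the selected model by default with
`chain_filter` to narrow — deposited entries are often multimeric and the
choice between monomer and multimer is left to the user).

## Numerical choices

* All electrical arithmetic is in SI units; Å-scale geometry is converted
  once, at element assignment, to avoid scattered unit factors.
* Linear solves use dense complex LU (LAPACK via `solve()`) on the reduced
  node-admittance matrix. Networks here are $10^2$–$10^3$ nodes, where
  dense direct solves are exact and fast; singular systems are reported as
  typed errors, never regularized silently.
* Components not touching the contacts are floating and excluded from the
  solve; links internal to a contact set are electrically invisible.
  Disconnected contacts are a first-class result (`Inf`) in scan contexts
  and a typed error (`inpa_disconnected`) in single solves.
* Link admission uses strict inequality $l_{ij} < R_C$; a pair exactly at
  the boundary is excluded. Coincident nodes are rejected as malformed
  input rather than given infinite conductance (the elemental impedance
  degenerates; real Cα traces never coincide).
* The two WKB branches do not meet continuously at $eV = \Phi$ (the
  matching used between them is not standardized). The default is the
  hard switch, with the direct expression applying at equality so that
  $P = 1$ there; an optional `blend` mode rescales the injection branch to
  join continuously (capped at 1). Regime *classification* counts
  $eV \ge \Phi$ as injection, so a single-link toy crosses over exactly at
  $V = \Phi/e$.
* Drops enter the probability as magnitudes: barrier transmission does not
  depend on the sign of the bias across a link.
* Barriers are quenched disorder — drawn once per realization, truncated
  at $\Phi > 0$ by rejection (a 69 ± 44 meV Gaussian has non-negligible
  negative mass, which is unphysical). `phi_sigma = 0` bypasses the draw
  entirely, so the single-barrier model is reproduced bit-for-bit under a
  given seed.
* Voltage points of a sweep start afresh from the all-high state (no
  hysteresis between sweep points); whether activated links should persist
  across bias steps is physically unresolved, and the fresh start is the
  conservative choice.
* The recorded injection fraction classifies activation *draws*: among
  links drawn into the low state, the share whose drop at draw time was
  over the barrier. (Classifying already-activated links by their drop
  would be vacuous — activated links are nearly shorted and carry almost
  no drop.)
* Past the structure's diameter the link set is complete and frozen, but
  the areas $A_{ij} \approx \pi R_C^2$ keep growing, so the absolute
  $Z(0)$ decays as $R_C^{-2}$ while every impedance ratio and spectral
  shape is invariant. The saturation diagnostics therefore report the
  frozen topology and the $Z(0) R_C^2$ scaling rather than absolute
  constancy — consistent with treating relative change as the model's
  output.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical configuration and seed give byte-identical
  outputs.

## Verification strategy

The network solver is checked against closed forms and independent
oracles: a single-link network must equal the elemental impedance, a
triangle of equal resistors the series-parallel value $2R/3$, small random
networks a pseudoinverse-based two-terminal computation, and any
uniform-dielectric network the exact factorization
$Z(\omega) = Z(0)/(1 + i\omega\tau)$ with $\tau = \rho\varepsilon\varepsilon_0$
(whose Nyquist curve is the unit-diameter semicircle after normalization
to the static value). Kirchhoff residuals at internal nodes are recomputed
from raw link currents and required below $10^{-9}$ of the injected
current; contact swaps must leave $Z$ unchanged (reciprocity). The
tunneling probability is compared to constant-level evaluations over a
grid of lengths, barriers and drops, and the Monte-Carlo sweep to a
from-scratch replay of the documented update scheme. Limits (frozen
barrier, equal resistivities, dominant leakage) must reduce exactly to the
linear law.

Tests and the acceptance script run at desk scale — helices of 10–40
residues, bundles of ~42, random chains of up to 200 nodes, 100
Monte-Carlo realizations with 60–200 iterations — sizes chosen so the
whole suite completes in seconds while every property above is exercised
on non-trivial topologies.

## Known limitations

* The dielectric table ships flat ($\varepsilon = 4$) because published
  residue-specific values are not reproduced here; results report which
  table was used.
* $\rho_{\mathrm{low}}$, the update schedule (synchronous redraw) and the
  burn-in fraction are model knobs, not measured quantities; sensitivity
  to them is part of the test surface but conclusions should not hinge on
  their exact values.
* Contacts are ideal; no electrolyte double-layer, constant-phase or
  transmission-line elements, and no frequency-dependent or
  temperature-dependent material response.
* The mapping is Cα-only: side-chain contacts, solvent and hydrogen
  bonding enter only implicitly through $R_C$.
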