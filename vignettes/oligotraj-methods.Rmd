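---
title: "Methods: contact, oligomerization and binding-kinetics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, oligomerization and binding-kinetics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotraj)
```

`oligotraj` analyses simulation trajectories of short amyloidogenic
peptides interacting with an inhibitor protein. This vignette documents the
model and its conventions, the tunable parameters, the synthetic-data
generators used for validation, and the numerical and design choices that
were genuinely open.

## The contact model

All downstream quantities derive from one primitive: two residues are **in
contact** when the minimum distance between their heavy atoms is at most
the cutoff (default 5 Å), computed under the minimum-image convention for
an orthorhombic periodic box. Conventions:

* **Boundary inclusive.** A distance exactly at the cutoff counts as a
  contact. The effect is measure-zero on real data but must be pinned down
  for reproducibility.
* **Residue-pair counting.** "Number of contacts" between two chains means
  the number of residue pairs in contact, because the contact is defined at
  residue level via heavy atoms. A heavy-atom-pair count is available via
  `chain_pair_contact_count(..., count = "atom")` for users who prefer the
  atom-pair reading of contact-count distributions; the two differ only by
  a monotone rescaling of histogram axes.
* **Minimum image, orthorhombic only.** Triclinic cells are unsupported.
  When a box edge is smaller than twice the cutoff the image assignment is
  ambiguous; the package warns and proceeds.

The production kernel is a cell list (cell size ≥ cutoff, atom-centric
neighbor enumeration) in C++; systems below 200 atoms, non-periodic frames
and boxes smaller than three cells per dimension fall back to a brute-force
scan. A second, fully independent brute-force implementation in pure R
(`residue_contacts_brute`) serves as the oracle: the test suite checks
exact pair-set equality on hundreds of randomized multi-atom-residue
fixtures, including coordinates far outside the primary cell.

## Oligomers, complexation and species classes

Peptide pairs sharing **more than five** residue contacts (strictly greater,
i.e. ≥ 6) are joined by an edge; oligomers are the connected components of
this graph (isolated peptides are monomers). A peptide is
**inhibitor-complexed** in a frame when it forms more than five contacts
with the inhibitor *entity* — the union of all inhibitor chains, so the two
domains of a dimeric inhibitor count jointly. An oligomer is complexed when
at least one member is: the per-member rule identifies the peptide that
attaches, not every member of the attached cluster.

Species classes follow the monomer / small (n = 2–5) / large (n > 5) size
convention, crossed with the complexed flag, plus a binary per-frame
"uncomplexed inhibitor" indicator (1 when no peptide is bound). Counts are
classified per frame and averaged within consecutive time bins (default
50 ns); a trailing partial bin is reported with its own frame count and
flagged in the metadata. Cross-run summaries are unweighted per-bin means.
For inhibitor-free control systems the complexed classes are structurally
zero and the inhibitor indicator is `NA`.

## Survival-time correlation and residence times

For each peptide, b(t) = 1 when it is complexed in the frame at time t.
Before correlation, unbound gaps **strictly shorter** than the escape
tolerance t₀ (default 1 ns) that are flanked by bound frames are bridged to
1; leading and trailing gaps are never bridged. Bridging is a
pre-processing pass rather than an on-the-fly allowance during origin
scanning — equivalent for this definition, simpler, and directly testable.
A gap of exactly t₀ is *not* bridged; that strictness at the boundary is a
declared convention. With t₀ = 0 the computation reduces to the strict
continuous-occupancy survival function, which the tests use as a degenerate
limit.

S(Δ) is the average over time origins t (every frame by default) of the
number of peptides bound at t and continuously bound over [t, t + Δ];
origins are restricted so t + Δ stays inside the run. S(0) is therefore
the average number of simultaneously complexed peptides, S is
non-increasing, and 0 ≤ S ≤ N. The stride-1 path is computed exactly from
bound-run lengths in O(frames); a direct-definition oracle validates both
it and the strided variant. Curves from several runs are averaged per lag
(unweighted), matching the within-run-then-across-runs averaging order.

Two residence-time estimators are provided: `exp_fit` (least squares on
ln S/S(0) over lags where S > 0.05·S(0)) and `integral` (trapezoidal
∫ S/S(0) dΔ, flagged as a lower bound when S has not decayed below
0.05·S(0) within the maximum lag). On two-state Markov data the
log-linear fit is unbiased by construction; the validation sweep
(k_off ∈ {0.01, 0.05, 0.2}/ns, k_on = 0.02/ns, 2 µs runs at 0.1 ns
spacing, five seeds) recovers 1/k_off within a few percent, well inside
the 15 % band the tests assert. With k_on = 0.02/ns about 2 % of unbound
gaps are shorter than 1 ns, so bridging inflates the recovered residence
time by ≲ 4 % — visible in the numbers but inside the band.

## Free-energy surfaces over contact counts

Per peptide per frame the pair (x, y) = (contacts with the inhibitor,
contacts with all other peptides) is recorded; samples are pooled across
peptides, frames and runs before histogramming (per-run surfaces remain
available by calling `pmf2d` on subsets). Then
W = −k_B·T · ln(P/P_max) with empty bins masked (infinite W) and excluded
from the minimum, so min W = 0 by construction. Defaults: bin width 1
contact, T = 325 K, k_B = 0.0019872041 kcal/mol/K (k_B·T = 0.6459
kcal/mol; the value is recorded in the output metadata since conventions
for k_B differ in the fourth decimal). The analytic oracle: samples from a
discretized 2-D Gaussian must produce a quadratic W matching the density
integrated per bin, with the 2σ bin at 2 k_B·T = 1.292 kcal/mol; the test
uses 10⁶ samples and σ ∈ {3, 4, 5} bins so that statistical error stays
below the asserted 0.15 kcal/mol.

`region_population` evaluates the fraction of samples in a predicate-defined
region (e.g. x ≥ 5 and y < 5, the inhibitor-bound-monomer corner). Such
fractions are properties of the trajectories analysed, not constants of
the method.

## Residue-level contact-probability maps

All maps are **conditioned fractions**: the denominator is the number of
qualifying observations, so probabilities are interpretable as "given a
complexed peptide-frame, how often does this residue pair touch". This
choice (rather than normalizing by all frames) is what makes statements
like "residue X contacts the inhibitor in ~100 % of bound frames"
well-defined; the conditioning is recorded in each map object and in the
TSV metadata so alternative normalizations can be layered on.

* **Inhibitor × peptide maps**: one observation per complexed
  peptide-frame, pooled over peptides, frames and runs (pool first, then
  divide — not a mean of per-run maps; per-run maps for dispersion can be
  obtained by mapping over runs).
* **Per-residue profiles** are any-contact probabilities accumulated from
  the same per-observation contact sets, not recomposed from map cells —
  the union of several pair events within one observation must count once.
* **Per-type profiles** average the any-contact probability over residues
  of each amino-acid type on the chosen side; types absent from the
  sequence are flagged absent rather than reported as zero.
* **Tertiary maps** show intra-peptide contacts with sequence separation
  ≥ 3 (the i±1, i±2 band is masked `NA`, not zero), for the complexed or
  the free population; in an inhibitor-free control system every
  peptide-frame belongs to the free population.
* **Quaternary maps** consider dimeric peptide combinations with more than
  five mutual contacts; the complexed population requires at least one
  member to be inhibitor-bound, the free population requires neither.
  Each unordered pair contributes both ordered observations, which
  symmetrizes the map exactly.

## Structural metrics

Superposition uses the Kabsch algorithm (SVD of the weighted covariance
with a determinant correction, so reflections are never returned);
near-collinear point sets trigger a conditioning warning. RMSD series
align each frame to a reference over an atom selection (Cα by default).
RMSF uses the **iteratively aligned mean structure** as reference (two
align–average–realign passes): the mean-structure convention is standard
for fluctuation analysis and is configurable back to a fixed-frame
reference. Per-residue RMSF averages the squared fluctuation over each
residue's selected atoms. A brute-force rotation search (Euler-angle grid
plus Nelder–Mead refinement) serves as the oracle on small point sets.

## The synthetic-data generators

The paper-scale system shape is built in as defaults: ten 26-residue
peptides (numbered 17–42 and carrying the Aβ17–42 sequence so residue- and
type-indexed outputs are exercised with realistic labels), one inhibitor
entity of two 85-residue domains, in a 124 Å cubic periodic box. Chains
are coarse-grained to one bead (the Cα) per residue. The inhibitor is a
spherical Fibonacci-lattice shell of radius 15 Å split into two
85-residue chains; its residue sequence is an explicitly synthetic cycle
through the 20 amino-acid types (no biological identity is claimed).

**Markov binding generator.** Each peptide's bound state evolves as an
independent two-state Markov chain (per-step switch probabilities
1 − exp(−k·dt); initial states drawn from the stationary distribution
unless specified). Bound peptides are docked as compact 5 Å-radius
bead-globules at one of 12 icosahedrally arranged surface sites — sites
are far enough apart that bound peptides never touch each other — and
unbound peptides are placed uniformly with ≥ 15 Å heavy-atom separation
from the inhibitor (the same minimum separation used to prepare the
simulated systems) and ≥ 10 Å from other peptides. Poses persist between
state switches; i.i.d. Gaussian jitter (σ = 0.3 Å) is added every frame.
If a fresh docking would crowd a drifting unbound peptide, that peptide is
re-placed (its state and contacts are unaffected). The bound template is
self-validated at generation time to give > 5 contacts with a wide margin
(≥ 7 residues within 4 Å), and the separation constraints make spurious
contacts unreachable under the jitter, so the emitted ground truth (per
frame, per peptide) is *exact* — the tests assert frame-by-frame equality
between generator bookkeeping and the analysis pipeline. Default rates
k_on = 0.02/ns, k_off = 0.01/ns give ~100 ns residences, the scale of the
complex lifetimes the analysis is meant to resolve.

**Oligomer scene builder.** Prescribed compositions (e.g. a bound trimer,
a bound dimer and five free monomers) are constructed geometrically:
members of an oligomer are stacked globules 8.5 Å apart (consecutive
members overlap enough for ≥ 6 mutual contacts, non-consecutive members
touch nothing), bound oligomers attach via exactly their first member, and
free groups are rejection-placed away from everything. Every scene is
self-validated through the contacts module before it is returned, so a
scene that cannot satisfy its own specification fails loudly instead of
producing silently wrong ground truth.

**Brownian toy.** An overdamped Langevin simulator (harmonic bonds,
soft-core repulsion, short-range Gaussian attraction, frozen inhibitor
shell with per-bead stickiness, periodic box) provides *emergent*
aggregation for integration tests: with zero attraction the system stays
monomeric; with strong peptide–peptide attraction in a small box large
clusters form. Two generators exist because exactness and emergence pull
in opposite directions: the Markov generator proves correctness, the toy
exercises the pipeline on data it did not script. Stability heuristic: the
stiffest chain normal mode feels ≈ 8× the bond constant, so the step must
keep (D/k_B T)·dt·8·k_bond below ~1; the defaults (k_bond = 2
kcal/mol/Å², dt = 5×10⁻⁴ ns, D = 50 Å²/ns) satisfy this with margin, and
any per-step displacement beyond 5 Å aborts with a diagnostic rather than
producing a blown-up trajectory.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: realistic peptide conformations and their
binding-coupled changes, diffusive (autocorrelated) motion between binding
events in the Markov generator, water and ions, secondary structure, force
fields, and any thermodynamic consistency between the binding rates and
the geometry. They validate the *analysis*, not the physics.

## Other design decisions

* **Heavy atom** = any atom whose element is not hydrogen, taken from the
  element column when present, else from the first alphabetic character of
  the atom name.
* **Histidine neutral at pH 7**; termini contribute +1/−1 that cancel in
  the total but are reported separately (`side_chain`, `n_term`,
  `c_term` attributes), so either convention for construct charges can be
  reconstructed.
* **Multi-chain inhibitors** form one logical entity by default; per-chain
  counts remain available in the chain-count matrices for per-domain
  reporting.
* **Uncomplexed-inhibitor indicator** is binary per logical inhibitor
  entity, not fractional per domain.
* **Configuration is the single source of thresholds** in the pipeline
  driver: the 5 Å cutoff, strict > 5 threshold, 50 ns bin, 325 K and
  t₀ = 1 ns all live in `run_config()` and are hashed into every output's
  metadata sidecar. The command-line surface is the R API plus the thin
  `inst/cli/oligotraj.R` wrapper.
* **Problem sizes used in validation:** contact-kernel oracle equivalence
  on 200 randomized 50-residue fixtures; residence-time recovery on
  fifteen 2 µs trajectories (three rates × five seeds); 10⁶-sample
  free-energy checks; frame-exact ground-truth comparisons on runs of a
  few hundred to 20 000 frames.

## Known limitations

Triclinic boxes, hydrogen-bond/salt-bridge/SASA contact definitions,
secondary-structure assignment, Markov-state or committor analysis, and
free-energy reweighting are out of scope. Trajectory input is limited to
the plain-text fallback format and DCD (via `bio3d`); XTC has no offline R
reader here. Residence times from single runs carry the usual
finite-sampling bias of survival fits; use several runs and the
`integral` estimator's lower-bound flag to detect censoring.
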