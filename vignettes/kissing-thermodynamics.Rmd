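---
title: "Coarse-grained thermodynamics of RNA kissing complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained thermodynamics of RNA kissing complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kisfold)
```

## The model

RNA tertiary motifs such as hairpin–hairpin kissing complexes are
stabilised by canonical helices whose thermodynamics are well measured,
but destabilised by loop-closure entropies that are *not* additive: the
two bridging loops of a kissing interface are constrained jointly by the
geometry of three stacked helices. kisfold estimates these entropies the
physics-based way, by exhaustive counting of chain conformations at
virtual-bond resolution, and combines them with nearest-neighbour helix
energetics into two-strand partition functions, melting profiles, and
free-energy landscapes for dimer systems.

The backbone is reduced to two pseudo-atoms per nucleotide (P and C4'),
connected by virtual bonds of 3.9 Å. Loop conformations are self-avoiding
walks of these virtual bonds on the diamond lattice, whose tetrahedral
bond angles approximate nucleic-acid backbone geometry; one nucleotide
contributes two lattice steps. Counting is exact: a depth-first search
enumerates every walk, excluded volume is a hard constraint (one lattice
site holds one virtual-bond junction), and the entropy is the logarithm
of the count, in units of $k_B$.

### Loop entropy of a kissing interface

For a kissing complex with stem lengths $H_1, H_2, H_3$ and loops
$l_1..l_4$ where $l_2, l_4 \le 1$ nt (which favours coaxial stacking of
$H_1$ on $H_2$ and $H_2$ on $H_3$), the entropic cost depends only on
$(H_2, l_1, l_3)$ and is computed in three steps:

1. The three stems are placed as one continuous ideal A-form duplex on a
   common axis; the eight anchor nucleotides of the bridging loops are
   read off the stem ends (`generate_anchor_frame()`). The anchors are
   therefore *regenerated from ideal geometry*, not taken from an
   experimental template — computed tables are qualitatively comparable
   to published Vfold-derived values but not bit-identical to them.
2. Each bridging loop of $l$ nt is enumerated as the set of self-avoiding
   walks of $2(l+1)$ steps between its snapped anchor sites.
3. Helix pseudo-atom sites are obstacles, so loop–helix excluded volume
   is exact at site resolution; the loop count is the product of the two
   anchored counts.

The penalty is measured against the free coil,
$\ln\omega_{\mathrm{coil}} = 2.05\,l + 0.1$ per loop:
$\Delta S = \ln(c_{l_1} c_{l_3}) - \ln\omega_{\mathrm{coil}}(l_1) -
\ln\omega_{\mathrm{coil}}(l_3)$ (in $k_B$). On our lattice mapping the
exhaustive coil counts grow with slope $2\ln\mu \approx 2.11$ per nt
($\mu \approx 2.88$ is the diamond-lattice connective constant), within
the quoted $2.05 \pm 0.15$; the *intercept* differs from 0.1 by up to
about one $k_B$ over the enumerable range, so tests check relative
agreement (≤10 %) and the slope, not the printed constants verbatim.

A transcription of the published $\ln\omega_{H_2,l_1,l_3}$ table ships in
`inst/extdata/entropy_table_vfold.tsv`; dash cells are explicit missing
values and two rows whose digit grouping was ambiguous in the extracted
source are flagged `note=ambiguous` and excluded from validation.

```{r entropy}
table_lookup(load_entropy_table(), 6, 2, 2)
kissing_entropy(kissing_topology(3, 5, 5))
```

### Helix geometry

An A-form helix has rise $h = 2.7$ Å/bp, radius $r = 9.9$ Å and 11 bp per
turn (the period is deliberately not configurable — it defines the phase
of the end-to-end formula). The strand end-to-end distance over $s$ steps
is

$$z(s) = \sqrt{(hs)^2 + r^2(1-\cos t)^2 + r^2\sin^2 t}
       = \sqrt{(hs)^2 + 4r^2\sin^2(t/2)}, \qquad t = \frac{2\pi s}{11}.$$

The reduction uses the chord identity
$(1-\cos t)^2 + \sin^2 t = 4\sin^2(t/2)$; note the *half* angle — a
version of the reduced form with $\sin^2 t$ circulates in print but is
not algebraically equal to the expanded form, and the builder's strand
ends only satisfy $z(s)$ under the correct half-angle reduction, so that
is what the package implements (both `form = "expanded"` and
`form = "reduced"` agree to machine precision).

The C4' wheel radius is solved from $(r, h,$ bond length$)$ so that both
virtual bonds have exactly 3.9 Å; the groove phase between paired
phosphates defaults to 2.147 rad (cross-strand P–P ≈ 17.4 Å).

### Closed-form energetics

* Pseudoknot penalty $G = \beta_1 + \beta_2 B^p + \beta_3 U^p$; the
  coefficients are experimental inputs with no defensible defaults, so
  `pseudoknot_params()` requires them explicitly.
* Freely-jointed-chain loop stretching $\beta G(N, M, z)$ with segment
  lengths $a = 6.2$ Å (single strand) and $b = 15$ Å (helix crossing),
  Flory radius $R_F = (N^{6/5}a^2 + M^{6/5}b^2)^{1/2}$. The printed
  "$\beta = k_B T$" is dimensionally inconsistent with $\beta G$ as an
  exponent; the standard $\beta = 1/(k_B T)$ is implemented. The constant
  2.4 Å is kept as a fixed model constant; $C_0$ defaults to 0 with a
  config override. At $z = R_F$ all three $z$-dependent terms vanish
  identically, and the slope there is $5/(2 R_F)$ (the log-term
  derivatives cancel the matching pieces of the linear coefficient), so
  the single interior well of the profile sits between the 2.4 Å cutoff
  and $R_F$.
* Helix stability comes from Turner-2004 stacking parameters
  (`inst/extdata/nn_stacks.tsv`, $\Delta G_{37}$ and $\Delta H$ per
  stack, duplex initiation, terminal A-U/G-U penalty). Temperatures other
  than 37 °C use $\Delta G(T) = \Delta H - T\Delta S$ with $\Delta S$
  recovered from the 37 °C values.
* All $k_B T$ conversions use $k_B = 0.0019872$ kcal/mol/K, defined in
  exactly one place (`kb_kcal_mol()`).

```{r energy}
kissing_complex_free_energy(c(-15.7, -15.7, -14.2), 8.62)
```

The worked total reproduces the printed −40.2 kcal/mol at 37 °C; the
8.62 $k_B T$ entropy there is treated as a printed input (our own table
cell (6,2,2) with the coil formula gives 8.4 $k_B T$, and the printed
value is sourced from a different parameter table).

## Two-strand ensembles

For strands short enough to enumerate exhaustively (≤ 30 nt combined),
`enumerate_structures()` lists *every* secondary structure — intra- and
intermolecular helices, at most one kissing interaction — and scores each
one. The partition function of the two-strand system is

$$Q = Q_1 Q_2 + e^{-\Delta G_{\mathrm{assoc}}/k_B T} Q_{12}, \qquad
\Delta G_{\mathrm{assoc}} = \Delta G_{\mathrm{init}} - k_B T \ln(C_T/4),$$

with $\Delta G_{\mathrm{init}} = 4.1$ kcal/mol (experimental) and both
strands at $C_T/2$ (the printed $C_T/4$ convention is used verbatim).
$Q_{12}$ includes an associated-but-unpaired state at zero energy by
default (`include_unpaired_bound`), since whether it belongs to the bound
or unbound sum is a convention; the flag exposes both readings. Sums are
accumulated in log space so energies of a few hundred kcal/mol cannot
overflow.

Model constraints and scoring choices, fixed once:

* **Minimum helix length 3.** With isolated 2-bp helices admitted, frayed
  and slipped registers of the toy dimers populate many isolated bins of
  the (native, non-native) landscape, each of which is trivially a local
  minimum on a sparse grid; a 40-design scan found no sequence family
  with a clean two-basin landscape. Requiring 3 stacked pairs (a common
  short-helix/lonely-pair threshold) removes these sub-stable registers
  and leaves the kissing vs extended-duplex phenomenology crisp.
* Minimum hairpin loop 3 nt; at most one kissing helix per structure;
  intramolecular pseudoknots and crossing intermolecular helices are out
  of scope at toy scale.
* Helices are scored by stack sums only — duplex initiation is priced
  once, by $\Delta G_{\mathrm{assoc}}$, not per helix.
* Hairpin/internal/multibranch loops are charged a conformational-entropy
  penalty computed by the package's own anchored lattice enumeration
  (cached by loop length; beyond 8 nt the enumerated value is extended
  with the standard $-1.75\ln(l/8)$ logarithmic tail). Turner loop tables
  are deliberately not used: the lattice entropies are the point of the
  model. A kissing interface uses the shipped entropy table when its cell
  exists; a dash cell marks the topology infeasible and removes the
  structure; topologies outside the table (e.g. fully paired loops,
  $l_1 = l_3 = 0$) fall back to the generic lattice penalties.
* Homodimer symmetry corrections are omitted; non-native means any pair
  absent from the reference, intramolecular pairs included.

The (native, non-native) landscape bins Boltzmann mass by the number of
reference-matching and non-reference pairs; bin free energies are
$-k_B T\ln(\mathrm{mass})$ and local minima are bins below all eight
neighbours (absent bins count as empty).

```{r landscape, eval = FALSE}
fx <- generate_fixture("two_minimum_dimer", seed = 1)
ens <- enumerate_structures(fx$sequences[1], fx$sequences[2])
land <- landscape(ens, fx$reference)
land[land$minimum, ]
autoplot(land)
autoplot(melting_profile(ens))
```

## What the synthetic fixtures emulate

Viral kissing-dimer sequences are not part of the package; the fixture
generator builds engineered stand-ins at desk scale:

* `kissing_dimer`: two hairpins (stem 3 bp, loop 5 nt) with
  reverse-complementary loops, so a 5-bp kissing helix can form.
* `two_minimum_dimer`: additionally the two strands are full reverse
  complements, so the kissing fold competes with the fully zipped
  extended duplex — the dimer can fold either way, and the landscape
  shows exactly two basins. The generator *verifies* this property by
  exhaustive enumeration at generation time and retries with fresh random
  sequences (bounded attempts) before failing loudly.

The 11-nt strand scale was chosen once: it is the largest scale at which
the fully reverse-complementary design remains exhaustively enumerable in
seconds (at 14 nt the run/mask combination space exceeds $10^{10}$).
These toys reproduce the qualitative physics — concentration-dependent
association, two coexisting dimer folds, entropy-limited kissing — but
not the quantitative stability of real viral dimerisation signals: real
loops are longer, real stems imperfect, and tertiary stabilisation
(non-canonical pairs, ion effects) is absent. Passing tests therefore
validate the machinery, not field-scale predictions.

## Numerical choices

* Lattice enumeration is exact, with deterministic (sorted) neighbour
  order, so counts and walk lists are reproducible without seeds. Free
  coils are counted with the first bond fixed (factor 4) and, from two
  steps, the second bond fixed (factor 3, the $C_3$ symmetry about a
  bond); anchored counts are absolute.
* The free-coil enumeration cap is 12 nt (24 steps, ~2×10^11 walks,
  minutes of CPU); beyond it the table interface must be used — the cap
  errors, it never truncates.
* `snap_to_lattice()` breaks distance ties toward the lexicographically
  smallest site and can be restricted to one sublattice so anchored-walk
  parity is always satisfiable.
* Anchored walks between helix phosphates use $2(l+1)$ steps for an
  $l$-nt loop (two bonds per nucleotide plus the two anchor-joining
  bonds); scaffold loop bridges run C4'→P with $2l+1$ steps.
* Scaffold assembly enforces a 3.5 Å clash distance between non-bonded
  pseudo-atoms (configurable); infeasible bridges abort with a clear
  message. Supported topologies are the empty structure, unpaired coils,
  single hairpins, full duplexes and kissing complexes with
  $l_2, l_4 \le 1$ — the assembly of arbitrary multi-helix junctions is a
  known limitation.
* Fixture generation is the package's only use of randomness; the seed is
  an explicit argument and the global RNG state is restored afterwards.

## Limitations

* Entropy tables computed here are "Vfold-like": anchors come from ideal
  coaxial geometry, not from an NMR template, so individual cells differ
  from published values even where the trends agree.
* The ensemble model has no salt dependence, no dangling ends, no
  non-canonical pairs, and no kinetics; partition functions are exact
  only because enumeration is exhaustive, which caps system size.
* N-way junctions and riboswitch-scale folds are out of scope.
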