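---
title: "natk methods: encodings, geometry, and screening metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{natk methods: encodings, geometry, and screening metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natk)
```

# Scope

`natk` implements the deterministic computational layers that surround
generative nucleic-acid backbone design: how a designer *states* a target
secondary structure (including pseudoknots, strand orientation, symmetric
pseudocycles and multi-chain strand exchange), how that statement is
*encoded* for a conditional generative model, how full-atom sugar-phosphate
backbones are *constructed* from internal coordinates, and how candidate
designs are *screened* quantitatively. The generative model itself (network,
denoising, sequence design, structure prediction) is out of scope: `natk`
produces the inputs such models consume and evaluates the outputs they
produce, via generic record tables.

# Secondary structures and pseudoknots

A secondary structure is a set of base pairs $(i, j)$, $i < j$, over $L$
nucleotides. **All nucleotide indices are 0-based and regions are half-open
`[start, end)`**, matching the arithmetic of submatrix placement and the
common pair-table dialects; R-level row indices (e.g. the `correspondence`
argument of `tm_score()`) remain 1-based as everywhere in R.

Dot-bracket strings are parsed with one stack per bracket layer, so layers
are matched independently and arbitrary-order pseudoknots can be expressed.
The layer alphabet is `()`, `[]`, `{}`, `<>`, then `Aa` ... `Zz` — the
community convention; no widely printed standard exists beyond the third
layer, so the tail of the alphabet is a documented package convention.
`&` and `+` are both accepted as chain separators; `&` is emitted.

Writing is the inverse problem: crossing pairs must be distributed over
layers. `write_dotbracket()` uses greedy coloring of the pair-crossing
conflict graph — pairs sorted by opener index, each assigned the lowest
layer it does not cross. Greedy layering is deterministic and linear-time;
it is not guaranteed minimal, but minimality is not needed for the
round-trip contract `parse(write(ss)) == ss`, which holds for any
single-partner structure that fits the alphabet. `pseudoknot_order()` is
defined operationally as (greedy layer count − 1): 0 for nested structures,
1 for kissing-loop-type knots, and so on.

Base triples and quadruplex pair sets (`multi_partner_allowed`) are valid
structures but cannot be written as dot-bracket; export fails loudly rather
than silently dropping pairs.

# The pair-conditioning tensor

Pairwise constraints are encoded as an $L \times L \times 3$ one-hot array:
`[1,0,0]` unspecified, `[0,1,0]` explicitly non-pairing, `[0,0,1]` paired.
The array is symmetric, and the diagonal is always unspecified — including
across chain boundaries; no special inter-chain channel exists, chain
breaks are carried as bookkeeping only.

Two policies are worth calling out:

* **Conflicts are errors.** Writing paired over non-pairing (or the
  reverse) for one cell raises a condition naming the cell; rewriting the
  same channel is idempotent. Silent last-writer-wins would corrupt
  templates built up from many region pairs.
* **Cells are independent.** A base may be paired with several partners
  (triple helices, G-quadruplexes) because each cell is constrained
  separately; only the dot-bracket exporter rejects such sets.

Region-level control: a `region_pair` is two equal-width, non-overlapping
intervals plus an orientation. Antiparallel regions pair
$(a_\mathrm{start}+k,\; b_\mathrm{end}-1-k)$ — the paired cells fall on the
anti-diagonal of the region submatrix — while parallel regions pair
$(a_\mathrm{start}+k,\; b_\mathrm{start}+k)$, the main diagonal. This is
the orientation dial for triple helices and quadruplexes. The encoding is
mirror-symmetric in the two regions and idempotent under repetition.

`from_secondary_structure()` exposes both readings of loop enforcement:
with `unpaired_as_nonpairing = FALSE` (default) only the listed pairs are
constrained; with `TRUE` every cell between two unpaired positions is set
to non-pairing, which forbids any alternative pairing among loop residues.
Both are legitimate conditioning styles; the flag avoids baking in a guess.

Strand exchange: `strand_exchange_template()` concatenates chains into one
global index space and encodes each duplex block as a region pair, so one
chain can pair blocks with two or more partner chains —
Holliday-junction-like topologies that control long-range connectivity in
multi-chain designs. The function returns both the tensor and the
equivalent multi-chain secondary structure.

Serialization: a dense container (text header: magic, `L`, chain breaks,
encoding description; then $L^2$ raw bytes of channel indices) for
exactness plus a sparse `i TAB j TAB channel` text export for
inspectability.

# Pseudocycle templates

Pseudocycles — single-chain RNAs whose fold repeats $n$ nearly identical
subunits with symmetric pairing between them — are specified at the segment
level: an ordered 5'→3' list of segments (helix sides, loops, hinges) with
inclusive length bounds, intra-subunit partner edges, inter-subunit edges
(subunit $s$ to $s+1 \bmod n$), and the symmetry order. The workflow is:

1. **Propagate** the subunit $n$ times into one chain (single-chain
   connectivity, not a cyclic multimer assembly); intra edges replicate,
   inter edges wrap modulo $n$. An inter edge with $n = 1$ is a topology
   error, since there is no distinct subunit to reference.
2. **Diversify** segment lengths by seeded uniform draws within bounds;
   segments tied by an edge share one draw, so partner regions always have
   equal width. A `target_total` is met by rejection sampling (default
   budget 10,000 attempts): simple, auditable, and exact — the feasibility
   pre-check is the interval $[n\sum\min,\; n\sum\max]$, and a target
   inside the interval that happens to be unreachable (e.g. not divisible
   by $n$) surfaces as the attempts-exhausted error rather than being
   silently adjusted.
3. **Realize** the template: global intervals in 5'→3' order, every edge
   becomes an (antiparallel unless declared parallel) region pair, and the
   secondary structure plus conditioning tensor are built. Kissing-loop
   inter-subunit edges that cross enclosing helices export with correct
   pseudoknot layering automatically.

By construction, an $n$-fold template with equal per-subunit lengths has a
pair map invariant under index rotation by $L/n$ — the pseudocyclic
symmetry the templates exist to express. Hinge segments belong to the
subunit they terminate; the packaged twofold example
(`example_topology_pc2_372()`) realizes two 186-nt subunits (three hairpins
plus a kissing-loop pair each) into a 372-nt, C2-symmetric, pseudoknotted
single chain. Hinge and kissing-segment length bounds are user parameters
with package-chosen example values; nothing in the toolkit asserts they
are canonical.

# Backbone geometry

## Frames

The per-residue frame follows the O4'-C1'-C2' atom convention: origin at
C1', first axis the unit vector toward O4', second the component of
C1'→C2' orthogonal to it, third their cross product. The atom triple is
fixed by the convention; the axis recipe (which atom is origin, which
difference is orthogonalized) is pinned by this package, as any concrete
implementation must.

## Internal-coordinate construction

`build_backbone()` places atoms sequentially by NeRF (natural extension
reference frame): each atom from a bond length, bond angle and dihedral
relative to three previously placed atoms, following the sugar-phosphate
connectivity graph. The free parameters per residue are the standard
backbone torsions α–ζ, the glycosidic χ, and a sugar pucker mode; all bond
lengths and angles come from a committed constants table
(`nucleic_geometry()`).

The sugar ring is handled as a **rigid pucker template**. The templates
(C3'-endo for RNA, C2'-endo for DNA, overridable per residue) were derived
once by embedding an ideal five-membered ring in 3D — pseudorotation
torsions at amplitude 38° and phase 18° (C3'-endo) or 162° (C2'-endo),
standard ideal bond lengths, ring closure solved exactly by Newton
iteration — attaching the exocyclic atoms (C5', O2', the glycosidic N) on
the correct faces, and measuring the NeRF parameters of each template atom
relative to the (C5', C4', C3') triad. Because the whole sugar is rigid
with respect to that triad, rebuilding from the frozen numbers reproduces
the embedding to machine precision, *including* the C2'-C3' ring-closure
bond, while γ, δ, ε, ζ, α, β and χ remain genuinely free. Dihedrals follow
the IUPAC sign convention (verified against an independent implementation).

Base atoms beyond the attachment point are out of scope: a generic
purine-style glycosidic nitrogen (named N9) and a single base reference
atom (named C4, placed by χ) are built, which is exactly enough for χ to
survive the build/extract round trip. Residue naming in PDB output is
sequence-agnostic (`N` for RNA, `DN` for DNA).

The 5'-terminal residue is built without its phosphate group, so α and β
of residue 1 and ε and ζ of the last residue are undefined (`NA` on
extraction). `extract_torsions()` measures the standard quadruplets and
recovers the construction inputs within $10^{-6}$ degrees; coordinates are
in ångström throughout.

## Ideal duplexes

`ideal_duplex()` generates regular fixtures by screw symmetry: a reference
residue is built with the constant A-form (RNA) or B-form (DNA) torsion
set, the screw transform between consecutive residues is measured, and the
strand is propagated with that fixed per-step twist and rise in the
helix-axis frame. The committed twist/rise values are therefore **the
helical parameters implied by the committed torsion and geometry tables**
(RNA: 34.03°/3.167 Å; DNA: 32.51°/3.615 Å), not textbook fiber values;
they are frozen at full precision and the fixtures reproduce them to
$10^{-6}$ Å, which is the property the tests assert. The second strand is
the first rotated 180° about an in-plane dyad and phased so paired C1'
atoms are 10.4 Å apart with the glycosidic atoms facing inward; residue
$k$ of strand 1 pairs residue $n-1-k$ of strand 2. No claim of
base-pair-level hydrogen-bond geometry is made — the fixtures exist to
exercise validation, torsion extraction and superposition code on
perfectly regular input.

## Superposition metrics

`kabsch_superpose()` is the standard SVD solution with the determinant
correction that excludes reflections. The test suite checks it against an
independent brute-force oracle: an exhaustive 15° Euler-angle grid
followed by derivative-free polish of the best cells (no SVD anywhere in
the oracle), agreeing within $10^{-3}$ Å on small point sets.

`tm_score()` implements
$\mathrm{TM} = \frac{1}{L_\mathrm{norm}} \sum_i \frac{1}{1 + (d_i/d_0)^2}$
with the molecule-class $d_0$: RNA mode $0.6\sqrt{L-0.5} - 2.5$ floored at
0.3 Å, protein mode $1.24\,(L-15)^{1/3} - 1.8$ floored at 0.5 Å, both
overridable via the `d0` argument. Score-optimal superposition has no
closed form, so the search is iterative: Kabsch fits seeded on the full
correspondence and on sliding contiguous fragments (half and quarter
length), each refined by re-fitting on the pairs within a distance cutoff
($d_0$, relaxed in 0.5 Å steps until at least three inliers) until the
inlier set stabilizes, keeping the best score over all seeds. The
correspondence is an explicit input — this package scores a given
alignment, it does not search for one — and `superpose = FALSE` evaluates
the sum in the given frame, which is what the single-pair closed-form case
uses (a free superposition would trivially zero one distance).
`coverage()` is $L_\mathrm{aligned}/L_\mathrm{design}$.

# Screening metrics

**Base-pair F1.** Precision $|\cap|/|P|$, recall $|\cap|/|D|$,
$F_1 = 2|\cap|/(|P|+|D|)$, with matches on exact $(i,j)$ identity. Two
empty sets score (1, 1, 1): predicting "no pairs" for an unpaired design
is perfect agreement (some conventions return 0 here; the choice is
documented). Exactly one empty set scores 0.

**Simulated reactivity.** Chemical probing (SHAPE-type) reactivity is high
at flexible/unpaired positions and low at paired ones. The simulator draws
each position from a mean-preserving log-normal,
$\mu \cdot \exp(\sigma Z - \sigma^2/2)$, around its class mean (defaults:
paired 0.1, unpaired 0.8, $\sigma = 0.3$) — non-negative and right-skewed
like probing data, exact class means at $\sigma = 0$, deterministic per
seed. What it deliberately does **not** emulate: sequence-dependent
reactivity biases, position-dependent normalization and outlier capping of
real pipelines, partially flexible paired termini, or correlated noise
along the chain. Tests passing on simulated profiles therefore show the
*bookkeeping and the estimator* are correct, not that any particular
experimental dataset would score well.

**Concordance.** Positions above a reactivity threshold (default 0.4,
between the default class means) are classified unpaired, and the score is
balanced accuracy against the design's paired/unpaired labels; degenerate
structures use the single defined class fraction. This is a deliberately
simple, documented surrogate for external probing-concordance scores whose
exact formulas are not public; it is named differently to avoid
conflation.

**Filtering.** `filter_designs()` applies strict inequalities — the
defaults are confidence pLDDT > 0.87, backbone RMSD < 2.2 Å, all-atom
RMSD < 3.5 Å — preserving record order. Strictness matters at the
boundary: a record at exactly 0.87 is rejected. Missing optional metrics
fail only bounds that reference them; pLDDT on the 0–100 scale is handled
by `plddt_scale = "percent"`. Filtering with no bounds is the identity and
adding a bound can never grow the output, which the suite checks as an
anti-monotonicity property.

**Sequence preparation.** `prepend_leader()` adds a 5' leader (default
`GG`, the T7 transcription-promoting leader, +2 nt) unconditionally — no
deduplication against an existing GG prefix, so synthesized lengths are
predictable.

# Numerical choices and problem sizes

* Torsion round trips are asserted at $10^{-6}$ degrees, frame and Kabsch
  identities at $10^{-8}$, fixture regularity at $10^{-6}$ Å; these are
  comfortable for double precision over the chain lengths involved.
* Randomized property checks use fixed seeds with 5–30 replicates per
  property, structures of 14–400 nt, point sets of 4–20 points, and a
  10,000-nt structure for the reactivity mean check; the packaged
  pseudocycle example is realized at its design size (372 nt). These sizes
  were chosen so the full suite exercises every contract in seconds while
  still covering the combinatorics (e.g. all 27 assignments of three
  3-valued segments, all 7 assignments at a fixed target).
* Degenerate inputs are first-class: empty pair sets, width-1 regions
  (orientation degenerate), single-base-pair duplexes, all-paired or
  all-unpaired structures in concordance, empty record tables.
* RNG state is saved and restored around every seeded operation, so
  library calls do not perturb a caller's random stream.

# Known limitations

* Greedy pseudoknot layering is not minimal coloring; `pseudoknot_order()`
  is defined relative to the greedy layering (they coincide on order-0 and
  the common order-1/2 motifs).
* The geometry tables are one self-consistent ideal parameterization, not
  a refinement target; sequence-dependent geometry, sugar repuckering
  dynamics and base-atom placement beyond the glycosidic attachment are
  out of scope.
* `tm_score()`'s iterative search is a heuristic (as all practical
  TM-score implementations are); the brute-force oracle bounds its error
  only on small instances.
* Thermodynamic folding, partition functions and structure prediction are
  explicitly out of scope: the toolkit manipulates *stated* structures.
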