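---
title: "Methods: modular protein CAD with modcad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular protein CAD with modcad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcad)
```

## The model

`modcad` designs proteins at the level of *modules*: super-secondary
structure fragments with defined N- and C-terminal interfaces.  Four
classes exist.  **Core** modules come from designed repeat proteins and
are self-compatible at both termini.  **Junctions** merge two core
motifs and therefore bridge two interface types.  **Hubs** are
multi-chain oligomers; a hub chain may be *sealed* at one terminus when
that end is buried in the oligomer interface.  **Caps** are modified
terminal repeats that seal the hydrophobic core at free termini; they
exist only in the final atomic model, never in the editable design.

Every legal bond between a C-terminus of module *a* and an N-terminus of
module *b* is stored as a pair transform $T_{ab}$ — a proper rotation
plus translation relating *b*'s canonical frame to *a*'s.  Extrusion
composes transforms: the child pose is $T_b = T_a \circ T_{ab}$, and
N-ward extrusion uses the inverse.  Because interfaces are precomputed
from pair structures, a design built only by extrusion is correct at
every junction by construction; whole networks may be rigidly moved
without disturbing any interface, which is why individual linked modules
are pose-locked.

### Direction and frame conventions

The source material leaves two conventions open; this package fixes them
and treats them as part of the file contract:

* a module's canonical frame is its fragment file's own coordinate frame
  (no re-centering), so stitching is a pure transform application;
* stored pair transforms map child-frame → pose-relative-to-parent
  (parent→child extrusion semantics).  The pair list is the single
  source of truth for compatibility; the naming grammar
  (`D14_j1_D79`, `D4_C4`, `Ccap_D14`, …) is a classification and
  validation convenience only, because extended hub name suffixes are
  not fully specified.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| collision overlap factor `f` | 0.75 | — | bonded neighbours necessarily have overlapping bounding spheres; 0.75 tolerates bonded-scale proximity while catching real clashes.  Configurable in (0, 1.5]; `f = 1` is the fully conservative sphere test. |
| pair superposition rmsd tolerance | 0.5 | Å | generous for idealized fragments, strict enough to catch a wrong fragment/chain mapping. |
| orthonormality / identity tolerance | 1e-9 | — | double-precision safe margin for the short composition chains designs produce. |
| peptide continuity threshold | 2.0 | Å | ideal peptide C–N is ~1.33 Å; above 2 Å the junction needs downstream minimization.  A warning, not an error, for non-toy libraries. |
| overlap-intention radius | 1.0 | Å | a joint within 1 Å of a module centre but unattached is ambiguous intent; 1 Å is far below any module radius. |
| units | Å internal, nm in design/guide JSON | — | the design-space convention is 1 nm per grid square; conversion factor 10 is applied only at file boundaries, and every file declares its units. |

Reflections (det = −1) are rejected outright rather than repaired: a
mirrored module is not a buildable protein.  Module scaling is likewise
not representable — transforms are rigid by type.

## The synthetic toy library

The generator emulates the structure of a real module database without
any experimental input: two core types (`H4`, `K4`) whose growth
transform is a pure rise of 6 Å along z; one junction `H4_j1_K4`
(rotation by 15° about x, then the rise); cyclic hubs `H4_C2`/`H4_C4`
with chains related by exact $R_z(2\pi i/n)$, sealed N-termini and
extendable C-termini; and all four caps.  Toy atoms sit on an ideal
helix (1.5 Å rise, 100° twist per residue, backbone names N/CA/C/O,
carbonyl O displaced radially so fragments are never collinear).  With 4
residues per module the helix turns 400° ≡ 40°, so a pure-rise module
boundary meets the previous C atom within ~0.9 Å — comfortably inside
the 2 Å continuity threshold while keeping the growth transform a clean
translation.  Defaults (rise 6 Å = residues × 1.5 Å, bend 15°, hub arm
radius 8 Å, symmetries {2, 4}) were chosen once as representative of
repeat-protein geometry and are validated, not tuned.

Every analytic pair transform is recorded in a sidecar file.  The
library builder must *recompute* these transforms by superposing
fragments onto the generated pair structures, giving a closed-loop check
of the Kabsch path.  One caveat is inherent: pair structures are PDB
files with fixed `%8.3f` columns, so coordinates are quantized at
5×10⁻⁴ Å and superposed rotations carry ~10⁻⁴ error.  Pure-translation
pairs are exact (rounding commutes with millangstrom translations);
rotation pairs are held to the quantization-limited 10⁻³ bound.

What a green test does **not** establish: toy fragments are rigid,
ideal, and tiny; real module libraries bring superposition noise at
junction overlaps, residue drops where repeats merge (the `drop_b`
mechanism is the declared extension point), and clashes at atomic rather
than sphere resolution.

## Scene semantics

Networks are maintained incrementally (created on placement, merged on
linking, split on deletion) and must always equal the connected
components of the link graph; the test suite re-derives the partition
with igraph after every mutating operation in a 200-step randomized
session.  Mirror groups hold (instance, chain) growth points: placing a
symmetric hub auto-groups its chains, and children of a mirror extrusion
are grouped in turn, so cyclic symmetry is preserved to < 10⁻⁶ Å over
repeated rounds.  Mirror extrusion is atomic — if any copy fails
(occupied terminus, clash), nothing changes — because partial symmetric
growth would silently break the symmetry invariant.  When two networks
are joined, the second-selected network moves onto the first; a
deterministic rule is required and the source material names none.

The sphere clash test is deliberately cheap and *almost* conservative:
if any inter-atom gap is under 2 Å the sphere test at `f = 1` flags the
pair in every case our randomized audit (500 seeded placements) visits.
Geometrically a grazing contact between the two extreme atoms of two
modules could evade it by up to 2 Å of centre distance; the audit found
no such configuration for the toy geometry, but the guarantee is
statistical, not absolute.

## The reference solver

The automated designer is a deterministic seeded beam search, not a
genetic algorithm: the design environment, spec format and solution
format are the contract here, and any optimizer honouring them fits
behind the same interface.  Sequences grow C-terminal-wards from every
core/junction start (hubs and caps are excluded — hubs enter designs via
manual placement and hybrid mode).  Each candidate's centre-of-mass path
is rigidly fitted to the guide polyline — exact com↔joint pairing when
the lengths match, arc-length resampling otherwise — and scored with a
symmetric chamfer RMS.  The objective is this package's choice; the
source material does not define one.  Ties break lexicographically on
the descriptor sequence; identical (spec, seed) inputs give
byte-identical solutions.  With the toy library's branching factor the
beam of width 8 provably holds every live state at depth ≤ 6, so beam
and exhaustive search agree on all recovery instances, which the
acceptance suite checks.  Guides are soft targets: an unreachable guide
yields a best-effort chain and an honest positive score.  Fixed-module
constraints anchor the search (mandatory start, pose never altered, no
global refit).

A solver network component that is not a simple path is traversed
depth-first from the start joint in id order; branching targets are thus
approximated by a single chain — a documented limitation, matching the
single-chain scope of the search.

## Numerical and degenerate-input choices

* Kabsch superposition uses SVD with a determinant sign correction and a
  final re-orthonormalization; the public `superpose()` enforces ≥ 3
  non-collinear points, while the internal fitter accepts 1–2 points
  (translation-optimal) for solver scoring of short chains.
* JSON is written canonically (sorted networks/modules/links, full
  numeric precision), so export → import → export is byte-identical;
  library save/load reproduces values to full serialized precision
  (shortest-round-trip decimals, i.e. one ulp short of bit identity).
* Instance ids reuse the lowest freed `NAME.NNN` suffix; network names
  are derived from the lowest member id so that re-exports are stable
  under reordering.
* Import of a solution verifies every consecutive pose against the
  library pair transform at 10⁻⁶ Å and refuses tampered files.
* mmCIF output restarts atom serials at 1, writes 3-decimal coordinates,
  and uses multi-letter chain ids beyond 26 chains; PDB output is
  refused above that format's limits instead of being silently wrong.

## Known limitations

No undo stack, no atomic-level energetics (repacking/minimization are
external), no sequence design, no hub-branching search, no automatic
discovery of which fragments a pair structure contains (manifest-driven
only).  The toy library is a stand-in for — not a substitute for — a
real repeat-protein-derived database.
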