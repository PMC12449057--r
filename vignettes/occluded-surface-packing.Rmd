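---
title: "Occluded surface packing: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occluded surface packing: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibos)
```

## The model

Atomic packing density measures how tightly an atom's van der Waals (vdW)
surface is enclosed by its neighbors. The occluded surface construction
makes this operational with three steps per atom:

1. **Surface dots.** The atom's vdW sphere of radius $r$ is covered with
   $n$ dots, each representing a patch of area $4\pi r^2 / n$ (the
   Fibonacci lattice assigns exactly equal areas; the classical radial
   lattice assigns each dot its latitude band's share). Dots that fall
   inside any other atom's vdW sphere are not part of the molecular
   surface and are removed first.
2. **Normals.** Each remaining dot casts a ray outward along the sphere
   normal. The ray stops at the first vdW surface of a neighboring atom;
   the distance travelled is the normal length $L$. If no surface is met
   within the diameter of a water molecule, $d_w$, the dot is
   *non-occluded* and disregarded — a water molecule could sit there, so
   the patch faces solvent rather than packed protein.
3. **OSP.** With $A_d$ the dot areas, the occluded surface packing
   density of an atom is
   $$\mathrm{OSP} \;=\;
   \frac{\sum_{\text{occluded}} A_d \,\bigl(1 - L_d / d_w\bigr)}
        {\sum_{\text{retained}} A_d},$$
   a dimensionless quantity in $[0,1]$: 0 for an isolated atom, 1 for an
   atom whose whole exposed surface touches neighbors at zero distance.
   Residue OSP is the unweighted mean over the residue's atoms (an
   exposed-area-weighted variant is available via `areaWeighted = TRUE`),
   and a structure is summarized by the mean and sample SD of its
   residue OSP values.

Buried, well-packed atoms accumulate many occluded dots with short
normals and OSP near the top of the range; atoms at cavities or chain
termini keep long or absent normals and score low. The two normalization
choices that the literature leaves open are made explicit here: the
denominator is the *retained* (exposed) dot area, not the full sphere
area, and occluded contributions are down-weighted linearly in $L/d_w$.
Both choices are configurable in the sense that the per-dot records are
returned and any alternative aggregate can be recomputed from them.

## Dot lattices

The classical implementation distributed dots radially about a fixed
reference axis: latitude bands equally spaced in polar angle, each band
carrying dots equally spaced in azimuth, with counts proportional to the
band circumference. This layout is axis-anisotropic — with $\sqrt{n}$
bands the azimuthal spacing runs about $4/\pi$ times the polar spacing,
all bands share the $\varphi = 0$ meridian seam, and per-dot areas
differ between poles and equator (`radialDots()`).

The default lattice replaces this with the golden-angle spiral
(`fibonacciDots()`): dot $i$ of $n$ sits at height
$z_i = 1 - 2(i + \tfrac12)/n$ and azimuth $\varphi_i = i\,\pi(3 - \sqrt 5)$.
The half-offset keeps dots off the poles; every dot carries exactly the
area fraction $1/n$; nearest-neighbor spacing is markedly more uniform:

```{r lattice}
nn_cv <- function(cl) {
  P <- dotPoints(cl); D <- as.matrix(dist(P)); diag(D) <- Inf
  nn <- 2 * asin(pmin(1, apply(D, 1, min) / 2))
  sd(nn) / mean(nn)
}
c(fibonacci = nn_cv(fibonacciDots(500)), radial = nn_cv(radialDots(500)))
```

Because the two lattices are different quadratures of the same surface
integral, OSP computed with either converges to the same value as the
dot density grows; the test suite checks this on the coordination-shell
fixture across densities 2 to 16 dots/Å².

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `density` | 5.0 | dots/Å² | ≈180 dots on a carbon atom; halving it roughly doubles the Monte-Carlo-like discretization error of per-atom OSP while halving run time |
| `dW` | 2.8 | Å | diameter of a water molecule, the standard occlusion cutoff: a gap wider than one water is solvent, not packing |
| vdW radii | bundled table | Å | Bondi-style element fallbacks (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80) with per-`RES:ATOM` overrides; editable plain-text config |
| `method` | `"fibos"` | — | spiral lattice; `"os"` reproduces the axis-referenced behavior |
| `keepHydrogens` | `FALSE` | — | experimental structures and computed models differ in hydrogen content; comparisons must run on the common heavy-atom set |
| `includeHetero` | `FALSE` | — | waters and ligands change packing materially (models are usually apo and water-free), so their inclusion is an explicit analysis decision |
| `madK` | 3 | — | influence flagging threshold, median + 3·MAD; larger is stricter |

## The comparison stage

Two conformers of the same chain are paired residue-by-residue on
(chain, sequence number, insertion code, residue name); residues present
on one side only are reported, never silently dropped. On the paired
residue OSP values the package computes:

* a two-sided **Wilcoxon signed-rank** test on the differences — exact
  null distribution (by convolution over doubled mid-ranks, valid under
  ties) up to $n = 25$ non-zero differences, tie- and
  continuity-corrected normal approximation above; zero differences are
  dropped, following Wilcoxon's original convention;
* paired **Cohen's d** $= \overline{\Delta} / s_\Delta$;
* the dispersion gap $\mathrm{sd}_b - \mathrm{sd}_a$ and a per-residue
  **influence score** for it. The default estimator is the jackknife
  (statistic on all pairs minus statistic without pair $i$); the
  analytic influence function of the SD,
  $\mathrm{IF}(x) = ((x-\mu)^2 - \sigma^2)/(2\sigma)$, scaled by
  $1/(n-1)$, is available as `mode = "analytic"`. Residues whose score
  exceeds median + `madK`·MAD are flagged as driving the excess
  dispersion of side b.

The side whose dispersion is attributed is exposed (`side = "a"`,
`"b"`, or the default `"gap"`); the gap is the default because
deterministic between-residue packing differences cancel there, leaving
the signal that differs between conformers.

## What the synthetic fixtures emulate — and what they do not

All tests run on generated sphere clusters with legal PDB naming
(ALA/CA), so the full stack including file I/O and radius assignment is
exercised without external downloads:

* `makeDimer(r, d)` — the two-body geometry with closed-form answers:
  buried-dot fraction $(1 - d/2r)/2$ per atom under overlap, zero
  occlusion once the surface gap exceeds $d_w$.
* `makeShell(r, n)` — a buried atom: a central sphere with $n$
  contact-distance neighbors on spiral directions.
* `makeLattice(k, spacing, jitter)` — a protein-core stand-in: $k^3$
  atoms on a jittered cubic lattice. The defaults (3.1 Å spacing for
  1.7 Å radii, 0.25 Å jitter, seed 99) put typical contacts slightly
  inside vdW overlap and give a realistic spread of per-residue packing.
* `makePerturbedPair(base, sigma, nOutliers, outlierShift)` — the
  experimental-vs-model pair: side b adds isotropic coordinate noise
  (default $\sigma = 0.05$ Å, the scale of coordinate uncertainty in
  well-refined structures) and displaces chosen atoms by 6 Å away from
  the centroid, the way a mispacked surface side chain extends away from
  its contact cluster. Pure random displacement directions were
  rejected: they frequently leave the displaced atom as packed as
  before, which makes "recovery of the planted residue" an ill-posed
  check.
* `bruteForceOcclusion()` — the independent oracle: per-dot, all-atom,
  no spatial index, no shared code path with the engine's vectorized
  cell-list traversal.

These fixtures deliberately do **not** model covalent geometry, residue
chemistry, secondary structure, crystallographic waters or B-factors.
Passing tests demonstrate that the geometry engine, the OSP aggregation
and the comparison statistics are correct on known ground truth — not
that any particular biological conclusion holds for real proteins.

## Numerical choices and degenerate inputs

* Ray casting takes, per neighbor sphere, the entry root
  $-b - \sqrt{b^2 - c}$ of the ray-sphere quadratic when positive; a
  positive exit root with non-positive entry means the origin is inside
  the sphere (occluded at length 0). Ties for the first hit go to the
  atom earliest in structure order, in both the engine and the oracle.
* Dots exactly on a neighbor's surface (distance $= r$) are retained by
  the burial filter; the subsequent ray cast decides their status.
* The neighbor index guarantees completeness with cutoff
  $2\,r_{\max} + d_w$, an upper bound on the center distance of any atom
  whose surface a normal can reach; queries are verified against
  all-pairs enumeration in the suite.
* Occlusion results are invariant under rigid motions when the dot
  lattice is co-rotated; regenerating the (structure-independent)
  lattice in a rotated frame may change individual dots by
  discretization, which is why the invariance test transports the
  clouds.
* An atom whose retained dot set is empty (surface fully inside
  neighbors) has OSP 0 by the empty-sum convention; a single-residue
  structure reports SD 0 with a `sd_degenerate` attribute; all-zero
  paired differences give $p = 1$, $d = 0$ by convention.
* Dot counts: $n = \max(1, \mathrm{round}(\rho\,4\pi r^2))$; the radial
  lattice lands within 20% of the request (bands are rounded), the
  spiral is exact.

## Problem sizes

The shipped suite and the acceptance script run entirely on fixtures of
2-64 atoms with 70-1000 dots per atom: oracle-equivalence sweeps use 25
random clusters of 5-20 atoms at 200 dots/atom, the screening study uses
the 27-atom lattice core at density 5 with 20 replicates per condition.
These sizes were chosen so every check recomputes from scratch in
seconds while keeping dot-sampling error well below the tested effect
sizes; the engine itself has no size-dependent logic beyond the cell
list, whose correctness is verified independently of scale.

## Known limitations

* Packing values depend on the radii table; comparisons are only
  meaningful with a shared table, and no parity with any legacy
  implementation's numeric output is claimed.
* First-intersection semantics only: no re-entrant surface correction,
  no solvent-excluded (rolling-probe) surface, no periodic boundaries.
* The planted-outlier screening operates near its detection threshold by
  design: with the default MAD rule, arbitrary seed streams recover the
  planted residue exactly in roughly 70-100% of replicates and flag a
  median of about 4-7% of residues under a pure-noise null. Exact
  recovery of *every* planted case should not be expected on real
  structure pairs.
* PDB fixed-column input only (no mmCIF); no structure repair, hydrogen
  addition, or symmetry expansion.
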