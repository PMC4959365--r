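---
title: "Communication mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communication mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commap)
```

`commap` maps the communication architecture of a protein from a
conformational ensemble.  This vignette explains the underlying model, the
tunable parameters and their defaults, what the synthetic generators do and
do not emulate, and the numerical and design decisions taken where the
procedure left genuine freedom.

## The model

The working assumption is that residues communicate through two distinct
physical channels, and that both leave a signature in an equilibrium
ensemble:

* **Concerted local fluctuations.**  Residues that move together form
  compact clusters.  These are captured by principal component analysis of
  the Cα coordinate covariance (after least-squares superposition),
  truncated at the essential subspace (the smallest mode count explaining
  at least 80 % of the variance — inclusive, so an exact 80 % counts).
  Local Feature Analysis re-expresses the retained eigenvectors residue by
  residue: `Corr(i,j)` sums, over the three coordinate components and the
  retained modes, the products of the eigenvector loadings of the two
  residues.  With the complete basis this is exactly `3·I`; truncation
  leaves sparse off-diagonal structure around a set of highly fluctuating
  seed residues.
* **Stable mechanical linkage.**  Residues connected by persistent
  non-covalent interactions whose mutual distance barely fluctuates relay
  perturbations efficiently.  The communication propensity
  `CP(i,j)` is the population variance (divide by the number of frames
  `F`) of the Cα–Cα distance; interactions are hydrogen bonds and
  hydrophobic contacts with HBPLUS-style geometric criteria, aggregated
  into per-residue-pair persistence fractions `INT(i,j)`.

Cliques formalise the first channel: starting from a seed, residues within
3.7 Å (mean inter-residue minimum distance) are added greedily as long as
the clique's mean pairwise correlation stays at or above `corr_cut`.
Communication pathways formalise the second: simple paths whose
consecutive residues are non-adjacent in sequence (separation ≥ 2 within a
chain), interact persistently (`INT ≥ int_cut`) and communicate
efficiently (`CP ≤ cp_cut`), with the transitivity requirement that *all*
residue pairs of a path satisfy the CP condition.  Both component types
are unioned over replicate ensembles into the Protein Communication
Network; its connected components, restricted to one edge colour (and for
pathway edges to a minimum supporting-path length), are the communication
blocks.

## Parameters

| Parameter | Units | Default / rule | Rationale |
|---|---|---|---|
| variance target | fraction | 0.8 | essential subspace convention for PCA of protein fluctuations |
| `corr_cut` | — | 5 % of off-diagonal upper-triangle `Corr` values lie strictly above | keeps only the strongest concerted-motion signal |
| `cp_cut` | Å² | smallest MCP value with `frac(MCP < c) ≥ p_ss` | residues in stable secondary structure are assumed to communicate efficiently with their sequence neighbours |
| `int_cut` | fraction | largest grid value (0.25–1.00, step 0.05) with maximal largest-component size | removes incidental contacts while keeping the interaction graph as connected as persistent contacts allow |
| `mpl_cut` | residues | n in 4–8 with the largest LCC reduction; ties → smallest n | separates short- from long-range communication |
| clique distance | Å | 3.7 (strict `<`) | contact distance for concerted clusters |
| seed separation | residues | ≥ 6; closer pairs keep the larger Cα RMSF | avoids redundant seeds on one fluctuation peak |
| H-bond criteria | Å, ° | D–A ≤ 3.9, H–A ≤ 2.5 (inclusive), three angles ≥ 90 | HBPLUS conventions; "maximum distance" read as ≤, angles as ≥ |
| hydrophobic cutoff | Å | strictly < 3.9 between apolar atoms (C/S not bonded to N/O) | "lower than" read as strict |
| pathway depth cap | residues | 30 | enumeration bound, see below |
| convergence repeats | — | 5; lone reference: one half contributes < 1 % of its group | reduces the bias of random reference picking |

Every threshold can be overridden (`run_pipeline(overrides = ...)`, or the
corresponding CLI flags), and the scan curves behind `int_cut` and
`mpl_cut` are exported with the parameter report.

Two readings of the published rules were genuinely open and were resolved
as follows:

* **Clique acceptance normalisation.**  Dividing the full double sum of
  pairwise correlations by `|S|` grows linearly with the clique size, so a
  fixed threshold could not terminate the extension; the acceptance
  statistic used here is the mean over unordered distinct member pairs,
  the only scale-free reading.  The literal form remains available via
  `grow_clique(normalization = "literal")`.
* **`cp_cut` distribution.**  The quantile is placed on the distribution
  of the modified communication propensities (MCP), not on the raw CP
  values, matching the proportion rule as stated; `MCP(i)` always divides
  by 8, which down-weights chain termini (deliberate, and logged by the
  functions as a documented property rather than warned about).

## Numerical choices and degenerate inputs

* Internal residue indices are 1-based and contiguous (the R idiom);
  author numbering (chain, resno, insertion code) is restored in every
  report and PyMOL selection.  Units are Å and ps throughout.
* Superposition fits every frame on the Cα atoms to the iteratively
  refined mean (tolerance 1e-6 Å on the mean, at most 10 iterations,
  starting from the current ensemble mean so an already-superposed
  ensemble is a fixed point).
* Discrete quantiles (`corr_cut`, `cp_cut`) use the
  smallest-value-satisfying-the-fraction rule; exact proportions are not
  attainable on discrete data.  The `int_cut` grid is rounded to remove
  floating-point drift from `seq()`.
* Tie-breaks are deterministic everywhere: clique candidates by highest
  new mean correlation, then smallest distance to the clique, then lowest
  index; secondary-structure types by `alpha > beta > turn`; `mpl_cut`
  ties toward the smallest n; block labels A, B, … by decreasing size.
* Degenerate inputs degrade with warnings instead of failures: a constant
  correlation matrix returns its value as the cutoff; `p_ss = 0` (no
  stable secondary structure, e.g. Cα-only models) sets `cp_cut` to the
  minimum MCP; an all-singleton interaction scan returns 1.00; a network
  without pathway edges leaves `mpl_cut` undefined and the pipeline simply
  reports no pathway-based blocks.  A rigid ensemble (zero variance) is a
  hard error, as no mode decomposition exists.
* Pathway enumeration is an exhaustive depth-first search from every
  residue, neighbours in ascending index order, pruning any extension that
  violates the all-pairs CP constraint, capped at 30 residues per path.
  The cap is the only approximation; the thresholds keep real interaction
  graphs sparse enough that the bound is rarely reached.  No memoisation
  is attempted — correctness of the per-edge longest-path annotations is
  favoured over speed, and the test suite checks exact agreement with a
  brute-force enumerator on hundreds of random graphs.
* Pathways are stored compactly: per edge the longest supporting-path
  length, plus the set of residue pairs co-occurring in at least one valid
  path.  Segment-pair linkage (`PR_AB`) uses co-occurrence in one path —
  not mere graph reachability — because direct links are counted
  separately by `Cont_AB`.
* Secondary structure follows the DSSP hydrogen-bond formalism
  (Kabsch–Sander energy below −0.5 kcal/mol; helices from consecutive
  n-turns, strands from bridge patterns, turns from isolated n-turns),
  collapsed to alpha (H, G, I), beta (E, B), turn (T) and other.  The
  published description mentions backbone torsions, but DSSP itself is
  hydrogen-bond based; the H-bond rules are implemented and the
  helix fixture was validated against an independent DSSP implementation.
  Bends (DSSP state S) are not counted as turns.
* Missing amide hydrogens are a configuration error by default;
  `hydrogens = "place"` builds backbone amide hydrogens geometrically
  (1.0 Å from N along the C′(−1)–N–CA bisector).  Structures with no
  polar atoms at all (Cα models) skip hydrogen bonding silently and use
  hydrophobic contacts only.
* Replicates are superposed and analysed independently, each with its own
  thresholds (the scans are properties of one run); only the components
  are unioned.  Whether to concatenate replicates before PCA was left
  open by the published procedure; independent fitting avoids mixing
  convergence artefacts across runs.
* XTC/TRR input is not supported — no R reader exists — and is rejected
  with a clear message; multi-model PDB, DCD, AMBER NetCDF and mdcrd are
  read (the mdcrd reader auto-detects optional box lines).

## What the synthetic generators emulate

`make_two_domain_ensemble()` builds a Cα pseudo-protein: two zigzag traces
(consecutive residues 3.5 Å apart, second neighbours at 3.8 Å, everything
else beyond 3.9 Å) separated by 12 Å, with three motion terms per frame —
a shared Gaussian displacement for every consecutive residue pair
(locally concerted motion, default amplitude 0.5 Å), an anti-correlated
rigid hinge translation of the two domains (default 0.5 Å) and iid thermal
jitter (default 0.1 Å).  The geometry is chosen so that clique extension
can proceed along the chain while hydrophobic contacts exist only between
second neighbours, and the amplitudes so that both the hinge and the local
modes sit inside the 80 % essential subspace while mean contact distances
stay below the clique cutoff.  By construction, within-domain distance
variances are far smaller than cross-domain ones and correlations are
block-structured — the statistical signature the method assumes.  What it
does **not** emulate: side chains, realistic force-field kinetics,
anharmonic transitions, correlated solvent effects, or any secondary
structure (all residues report `other`, so pathway machinery stays off
unless thresholds are overridden).  Passing tests on this fixture
therefore demonstrate the recovery of designed correlation/contact
structure, not performance on real MD data.

`make_helix_ensemble()` builds an ideal α-helical backbone (φ = −57°,
ψ = −47°, standard bond geometry, amide hydrogens included) with optional
jitter — it exercises the DSSP-style assignment and hydrogen-bond
detection.  `make_hbond_geometry()` places a donor/hydrogen/acceptor/
antecedent quartet with exactly requested distances and angles (verified
to 1e-6°), which makes boundary testing of the geometric criteria exact.

Problem sizes used by the test-suite: random-graph oracles run on 200
graphs of up to 12 nodes; the domain-recovery check uses the generator's
default study condition of 60 residues with two replicates of 1000 frames;
the convergence checks use duplicated trajectories of 40–200 frames.
These sizes give exhaustive oracles and stable statistics while keeping
the full suite within a coffee break on one CPU.

## Known limitations

* Clique-based blocks can only contain residues incident to a
  correlation value above the 5 % cutoff that is shared within a clique;
  small proteins with very uniform correlation fields may yield sparse
  clique coverage.
* The pathway depth cap truncates enumeration on unusually dense
  interaction graphs (a message reports when the cap is hit in practice
  through the scan curves).
* Hydrogen placement is limited to backbone amides; side-chain donors in
  hydrogen-free models are not reconstructed.
* The convergence diagnostic assumes the two trajectory halves are
  comparable samples; it does not replace block averaging for estimating
  statistical error of individual observables.
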