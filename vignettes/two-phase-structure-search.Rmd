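---
title: "Two-phase structure similarity search: model and methods"
author: "foldscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase structure similarity search: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscan)
```

## The problem

Scanning a database of protein 3D structures for chains similar to a
query is quadratic in chain length per pair and linear in database
size, so most of the cost is wasted on chains that share nothing with
the query. `foldscan` implements a *filter-and-refine* strategy: a
cheap low-resolution alignment over secondary-structure elements prunes
the database, and only the survivors are aligned at residue level and
ranked. A final superposition step reports the geometric agreement
(RMSD) of the best hits.

## Structure representations

A chain of $q$ residues is represented twice.

**Reduced chain of secondary structures (phase 1).** Each residue
carries one of three codes — H ($\alpha$-helix), E ($\beta$-strand or
sheet), L (loop, turn, coil or undetermined) — and the per-residue
sequence is run-length encoded into $n \le q$ SE regions
$SE_i = [SSE_i, L_i]$ with type and length. Six consecutive helical
residues become one region $[H, 6]$.

**Molecular residue descriptors (phase 2).** Residue $i$ is the vector
$s_i = \langle |C_i|, \gamma_i, SSE_i, r_i \rangle$: the length of the
vector $C_i$ between the C$_\alpha$ atoms of residues $i$ and $i+1$,
the angle between $C_i$ and $C_{i+1}$, the secondary-structure code,
and the amino-acid type. $|C_i|$ and $\gamma_i$ are internal
coordinates, invariant under rigid motion of the chain, which is what
makes the alignment coordinate-frame-free. Features undefined at the
chain terminus ($|C_q|$; $\gamma_{q-1}, \gamma_q$) are zero-filled.

Secondary structure is taken from the PDB header's HELIX/SHEET records
(every helix class maps to H), not from a geometric assignment such as
DSSP: the three-letter alphabet collapses subtypes anyway, the loop
rule below treats everything non-regular leniently, and header records
keep the tool free of an external assignment step. Chains assigned by
different methods may therefore label boundaries slightly differently;
this shifts region lengths by a residue or two but is damped by the
length term in the phase-1 reward.

## The alignment engine

Both phases use the same local alignment with affine gaps over an
arbitrary reward $\rho(i, j)$ (Smith–Waterman/Gotoh form). With
$g_O \ge g_E \ge 0$:

$$
\begin{aligned}
E_{i,j} &= \max\{E_{i,j-1} - g_E,\; M_{i,j-1} - g_O\}\\
F_{i,j} &= \max\{F_{i-1,j} - g_E,\; M_{i-1,j} - g_O\}\\
M_{i,j} &= \max\{M_{i-1,j-1} + \rho(i,j),\; E_{i,j},\; F_{i,j},\; 0\}
\end{aligned}
$$

with zero boundary row and column, and the *Score* is the maximum cell.
Because each cell depends only on its three neighbours, the scan keeps
two rows plus the gap vectors — linear memory — and the full matrix is
materialised only when a residue-level path is requested
(`local_affine_matrix()` + `backtrack()`), i.e. for the few top hits.

Numerical choices the recurrence leaves open are fixed for
reproducibility: $E$/$F$ are $-\infty$ outside the matrix (a gap cannot
be extended before it is opened; any value $\le -g_O$ is equivalent
because cells clamp at zero), argmax ties break to the first occurrence
in row-major order, and backtracking prefers diagonal over vertical gap
over horizontal gap, ending a gap run as early as possible. The double
loop is compiled (Rcpp); reward matrices are built vectorised in R.

## Phase 1: low-resolution filter

The reward for pairing query region $i$ with database region $j$ is

$$\delta_{ij} = \sigma_{ij}\left(1 - \frac{|L_j^D - L_i^Q|}{L_j^D + L_i^Q}\right),
\qquad
\sigma_{ij} = \begin{cases}
1 & \text{both H or both E}\\
0.5 & \text{at least one L}\\
0 & \text{one H, one E.}
\end{cases}$$

$\delta \in [0, \sigma]$: identical types of identical length score
$\sigma$, and the reward decays with relative length difference. Since
a region's best partner is itself, the query's self-score
$Score^{QQ}$ has the closed form (number of H/E regions) +
0.5 (number of L regions) — the test suite checks the dynamic program
against this identity.

During a scan the $\sigma$ lookup goes through a *query profile*: for
each query region the coefficients against H, E, L and a neutral
padding element 0 are precomputed and byte-encoded ($0 \to 0$,
$1 \to 1$, $0.5 \to 2$). Scoring always uses the decoded real values;
the integer codes exist for compact serialisation. Neutral padding
elements score zero and provably cannot change a local-alignment
maximum, so padded and unpadded chains score identically.

A database chain qualifies for phase 2 when

$$Score^{QD} / Score^{QQ} \ge Q_t, \qquad Q_t \in [0, 1],$$

inclusive. $Q_t = 0$ disables the filter (every chain passes);
raising $Q_t$ can only shrink the qualified set. The default
$Q_t = 0.2$ filters aggressively while still admitting short local
similarities; for very short queries (under ~100 residues) the reduced
chain is so generic that filtering is hardly selective and $Q_t = 0$ is
a reasonable choice.

## Phase 2: high-resolution ranking

For qualified chains the same engine runs at residue level with the
descriptor reward

$$ss_{ij} = w_C\, e^{-(|C_i^Q|-|C_j^D|)^2} + w_\gamma\, e^{-(\gamma_i^Q-\gamma_j^D)^2}
 + w_{SSE}\, \sigma^{SSE}_{ij} + w_r\, \sigma^r_{ij},$$

where $\sigma^{SSE}$ reuses the three-valued rule above on the
residues' codes and $\sigma^r$ is BLOSUM62 rescaled globally to
$[0, 1]$ by $(v + 4)/15$ (min $-4$, max $11$ over the 20 standard
residues; the global min–max map was chosen over per-row or logistic
alternatives because it is the only one reproducible from the published
matrix alone). Unknown residues (`X`) get $\sigma^r = 0$. All weights
default to 1; $w_r = 0$ disables the sequence term when hunting purely
structural similarity. The reward is non-negative, so divergence is
penalised only through gaps and the local clamp — there is no explicit
mismatch penalty. The phase-2 *Score* ranks the hits; ties break by
chain id.

### Units of $\gamma$

Angles are stored in radians. The Gaussian $e^{-\Delta^2}$ has a
useful dynamic range only when typical differences are $O(1)$:
backbone angle differences span roughly $0$–$\pi$, giving similarities
from 1 down to $\approx 5\times10^{-5}$. In degrees the same
differences would collapse the Gaussian to zero for all but
near-identical angles, effectively deleting the angular term.

### Gap penalties

No canonical values exist for this scoring system, so the defaults are
chosen from the reward scales: phase 1 uses $g_O = 1.0$, $g_E = 0.1$
(one full region-identity reward to open a gap), phase 2 uses
$g_O = 2.0$, $g_E = 0.2$ (half the maximal residue reward of 4).
In both phases a single weak mismatch (reward $\le 1$) is cheaper than
opening two gaps around it, which keeps alignments compact. Both pairs
are user-configurable per call and through the CLI.

## Phase 3: superposition

For a reported hit the residue-level path is backtracked and the
C$_\alpha$ pairs are superposed by the Kabsch algorithm (SVD of the
covariance with determinant correction, so reflections are excluded),
giving $RMSD = \sqrt{\tfrac1N\sum_i d_i^2}$ over the $N$ aligned pairs.
Fewer than 3 pairs or collinear point sets are rejected as degenerate.
The tests cross-check the SVD route against an independent quaternion
(Horn) solver to $10^{-9}$, and against `bio3d`'s fitting only as an
external sanity reference.

## The database cache

`build_database()` parses every chain of a PDB directory once and
serialises records (id, reduced chain, descriptor chain, coordinates)
to a binary cache, sorted ascending by residue count, with a format
version and a nominal block size of 32 chains recorded as metadata
describing how records would be batched for parallel processing.
Scores never depend on the ordering or on padding — a property the
suite asserts by shuffling record order. The cache must be rebuilt
when the database contents change; a version mismatch or truncated
file is rejected at load.

## What the synthetic generator does and does not emulate

`make_trace()` builds chains region by region with idealised local
geometry: helices with 1.5 Å rise, 2.3 Å radius and 100°/residue,
near-linear strands with 3.4 Å rise and a small alternating pleat,
loops as seeded 3.8 Å random walks, consecutive regions joined at
3.8 Å. This reproduces exactly the features the descriptors measure —
local distances, angles and SSE runs — so it exercises every code path
of the pipeline. It does **not** emulate tertiary packing, sterics,
realistic loop ensembles, missing residues or assignment noise in real
PDB headers. Passing tests therefore demonstrate correctness of the
algorithmics and self-consistency of the scoring system, not retrieval
quality on real folds; the latter depends on the SSE assignment source
and on gap/weight tuning against curated benchmarks, which is out of
scope here.

The test and acceptance suites run at desk scale by design: random DP
instances up to 8×8 against an exhaustive reference, 100-chain
closed-form checks, a 200-chain database for the filter-monotonicity
property, 20-residue planted fragments for path recovery. These sizes
were picked so each property is checked in seconds while still probing
all boundary cases (single-residue chains, single regions, alternating
layouts, ties).

## Known limitations

- Secondary structure comes from header records; entries without
  HELIX/SHEET records degrade to all-loop chains, which phase 1 then
  scores uniformly at the 0.5 level.
- Only the first NMR model and the first-listed altloc conformer are
  read; mmCIF input is not supported.
- Phase 1 and phase 2 are fully independent — alignment paths are not
  transferred between phases, so the phase-2 optimum may use a
  different correspondence than the phase-1 one.
- The reward has no mismatch penalty; on highly self-similar inputs
  (e.g. long ideal helices) local alignments extend greedily and rank
  by cumulative reward, i.e. effectively by length within a similarity
  class.
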