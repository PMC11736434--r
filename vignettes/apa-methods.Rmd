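---
title: "Quantifying dynamic alternative polyadenylation from 3'-tag single-cell data"
author: "apadyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic alternative polyadenylation from 3'-tag single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apadyn)
```

## The problem

3'-tag single-cell RNA-seq reads pile up at transcript 3' ends, so the
positions of read 3' ends reveal which polyadenylation site (PAS) each
transcript used. Genes with several 3'UTR PASs produce isoforms with shorter
or longer 3'UTRs; a shift toward the proximal PAS (3'UTR shortening) is a
recurring signature of proliferation and of terminal differentiation in
blood. `apadyn` turns tag alignments plus a 3'UTR/intron annotation into:
called PAS peaks, artifact-filtered count matrices, proximal/intronic usage
indices, differential-usage tests between cell populations, and per-cluster
specificity calls — together with a fully seeded simulator so every stage is
testable against known ground truth.

## The model and its statistics

**Peak calling.** The upstream tooling this package stands in for does not
document its peak caller, so `apadyn` uses a transparent substitute: within
each annotated 3'UTR or intron interval, maximal runs of positions whose
tag-3'-end coverage reaches `min_coverage` (default 5), with gaps up to
`merge_distance` (default 25 nt) closed, become peaks. The strand-aware
downstream-most covered base is the peak's 3' edge (`edge3`), the inferred
cleavage position. Multimodal pile-ups inside one run are deliberately not
split; users can import externally called peak tables instead.

**Credibility filters.** Counts are normalized to CPM per cluster, with the
library size defined as the column sum of the assigned-count matrix (whether
raw or assigned totals were used upstream is undocumented; assigned totals
keep CPM computable from an imported count table alone). A 3'UTR peak is
removed when its summed CPM over all clusters is below 10, or when a run of
at least 8 adenines on the sense strand starts 10–140 nt downstream of its
3' edge (the footprint an oligo-dT primer can anneal to — internal priming).
Intronic peaks additionally require at least 5 CPM in every cluster and use
a 7-adenine run in a 1–200 nt window. "Starts in the window" anchors the
window test at the run's first base; windows truncate silently at chromosome
ends.

**Usage indices.** For a 3'UTR with peaks ordered proximal→distal and counts
$C_1, \dots, C_k$:

$$\mathrm{pPUI} = \log_2 \frac{C_1 + 1}{\langle C+1 \rangle}, \qquad
\langle C+1\rangle = \Big(\prod_{j=1}^{k} (C_j+1)\Big)^{1/k}$$

The pseudocount of 1 avoids zeros. Higher pPUI means more proximal usage,
i.e. a shorter 3'UTR. For an intronic peak with count $C_i$ and the gene's
summed 3'UTR counts $C_u$, $\mathrm{iPUI} = \log_2\,(C_i+1)/(C_u+1)$; higher
iPUI means more intronic cleavage. At cluster level both indices are always
defined (pseudocounted). At cell level a unit's entry is missing unless the
cell has at least one read in the unit: pseudocounting empty cells would pin
their pPUI at 0 and fabricate signal. The "proximal" peak of a >2-peak 3'UTR
is the single most-upstream peak; all peaks enter the geometric mean.

**Differential usage.** Each multi-PAS unit contributes a peaks × clusters
contingency table of raw counts; Pearson's chi-squared without continuity
correction (df $=(k-1)(m-1)$) tests homogeneity, and Benjamini–Hochberg
step-up q-values control the FDR across units. Units with an all-zero column
(or fewer than two non-empty peaks) are skipped and tallied rather than
patched, and all-zero rows are dropped from the table. In a pairwise
comparison a unit with $q < \alpha$ (default 0.05, applied uniformly to
3'UTR and intronic tests) is classified by the sign of the index change:
increase = shortening in the second population, decrease = lengthening.
The omnibus test over all clusters defines the "dynamic-APA" set. Trend
summaries compare per-cell average pPUI between groups with a Welch t-test
(the unit of replication is the cell; the source analysis does not state
one), and distribution comparisons use the two-sample Kolmogorov–Smirnov or
tie-corrected Kruskal–Wallis test.

**Specificity calls (ROKU-style).** Each unit's cluster vector $x$ is
processed as $x' = |x - \mathrm{tbw}(x)|$ where $\mathrm{tbw}$ is a one-step
Tukey biweight ($u_i = (x_i - \mathrm{median})/(5\,\mathrm{MAD} + 10^{-4})$,
weights $(1-u^2)^2$ for $|u|<1$); Shannon entropy of the normalized $x'$
scores nonspecificity (a constant vector is assigned the maximal
$\log_2 n$). Outlier codes $\{-1,0,1\}$ per cluster come from a search over
all splits with $s$ low-side and $l$ high-side outliers
($s+l \le n-2$), minimizing

$$\mathrm{AIC}(s,l) = (n-s-l)\,\ln \hat\sigma^2_{\text{inlier}} + 2(s+l+1)$$

with the MLE inlier variance; ties resolve toward fewer outliers, then
fewer low-side outliers. For pPUI, $+1$ marks a specifically shortened and
$-1$ a specifically lengthened 3'UTR; for iPUI, enhanced/attenuated intronic
cleavage. Stage-specific events average the index columns over a
user-supplied cluster→stage map before calling (the stage grouping is an
input, not re-derived). Pattern similarity between clusters is Pearson
correlation of the index matrix with average-linkage clustering on $1-r$.

Two properties of this outlier search deserve emphasis. First, it is not
scale invariant and calls spurious outliers on a noticeable fraction of
pure-noise vectors (about 6–12% of $N(0,0.1^2)$ 8-vectors receive a $+1$;
the characterization is asserted in the test suite). Per-cluster specific
sets therefore carry a background rate and should be read relative to it —
planted-recovery tests use a matrix of genuinely specific units and count
precision at the call level. We also verified against the reference
implementation of the procedure that this limitation is not an artifact of
our AIC variant: the published tool's stronger Ueda penalty shows the same
background behavior. Second, exact sign-flip antisymmetry
(negating $x$ swaps $+1$ and $-1$) holds for generic inputs but is
unattainable when mirror-image splits tie exactly in AIC, as happens for
perfectly symmetric (e.g. heavily rounded) vectors; such ties resolve toward
fewer outliers.

**qPCR validation.** Relative expression of a PAS-specific amplicon is
$\mathrm{RE} = E^{\,\overline{Cq}_{\mathrm{ref}} - \overline{Cq}}$ with the
amplification efficiency $E$ fixed at 2 (config-exposed; standard curves are
reported as linear upstream but without efficiencies). Comparing two cell
types, the composite ratio $(p_2/p_1)/(d_2/d_1)$ of proximal and distal REs
exceeds 1 under 3'UTR shortening in cell type 2; the verdict requires a
two-sided Welch t-test $p<0.05$ on replicate-level
$\log_2(\mathrm{RE}_p/\mathrm{RE}_d)$ values (the upstream figure shows
significance stars without naming a test). With a single replicate the
ratios are reported and the p-value is NA.

## What the simulator emulates

`sim_config()` states a world and a seed determines it completely:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 60 | genes, laid out half on each strand |
| `n_clusters`, `cells_per_cluster` | 4, 100 | a differentiation ordering |
| `mean_tags_per_cell_per_gene` | 2 | Poisson tag depth |
| `pas_per_utr` | (0.2, 0.6, 0.2) | P(1, 2, 3 3'UTR PASs) |
| `frac_shift_genes`, `shift_delta` | 0.5, 0.4 | planted proximal-usage ramp |
| `baseline_proximal` | 0.3 | proximal usage in the first cluster |
| `intron_pas_prob`, `intron_share` | 0.25, 0.2 | intronic PAS prevalence/usage |
| `artifact_rate` | 0.15 | genes with an A-rich artifact locus |
| `signal_offset`, `signal_prob` | 21, 1.0 | AATAAA plant position/fraction |
| `jitter_sd` | 5 | tag positional noise (nt) |

Genes have a fixed architecture (exon–intron–exon–3'UTR, 900 nt UTR, PASs
150 nt into the UTR spaced 200 nt apart) chosen so that every filter window
fits and artifact A-runs can never reach a true peak's window; configs whose
UTR cannot hold the requested spacing are rejected. Shifted genes ramp
proximal usage linearly from `baseline_proximal` to
`baseline_proximal + shift_delta` along the cluster ordering; stable genes
hold the baseline. AATAAA is planted ending `signal_offset` nt upstream of
each (signal-bearing) cleavage site; artifact loci get a 10-adenine run
starting 20 nt downstream and emit tags at `artifact_tag_mean` per cell.
Accidental sense A-runs of 7+ within 230 nt downstream of true sites are
scrubbed so the internal-priming filter has zero planted false positives.
The defaults mirror the recovery experiment the test suite runs: 30 shifted
vs 30 stable genes over a 4-cluster path at 100 cells per cluster. No
statement in the source analysis describes its data generatively; all
simulator parameters are free knobs of the package's own stated world, not
estimates of the real data.

What the simulator does **not** emulate — and a green test therefore cannot
establish robustness to: realistic expression distributions (all genes share
one Poisson depth), UMI duplication/collapsing, doublets and ambient RNA,
mapping artifacts other than internal priming, overlapping genes, and
multimodal cleavage around a single PAS.

## Numerical and interface choices

- Coordinates are 0-based half-open internally; BED is written verbatim, GTF
  converted at the boundary (1-based inclusive). Tag BED records carry
  `barcode:cluster` in the name field so plain BED6 is self-contained.
- Pipeline configs serialize to JSON (round-trip identity is tested); output
  tables carry `#` provenance headers (package version, config hash, seed).
- `alpha` comparisons are strict (`q < alpha`); at `alpha = 1` every unit
  with a non-degenerate table is direction-classified because `q = 1`
  exactly requires a chi-squared of 0, which also forces a zero index change.
- Ties for the "frequent" PAS of a 3'UTR (equal summed counts) break toward
  the proximal peak.
- A peak's assignment to gene and region follows the annotated interval it
  was called in; with overlapping annotations a 3'UTR interval takes
  precedence over an intron, matching the 3' bias of the protocol.

## Known limitations

- The coverage-run peak caller does not reproduce any external tool's exact
  boundaries and does not split merged multimodal runs.
- Cluster-level CPM filtering inherits whatever cluster imbalance the data
  has; the per-cluster "<5 CPM" intron rule is strict by design and can
  remove genuine low-abundance intronic peaks.
- The outlier-based specificity calls carry the background false-call rate
  discussed above; they rank and flag, they do not provide per-call error
  control the way the BH-corrected chi-squared tests do.
- Upstream-exon and intergenic PASs are out of scope, as are clustering,
  pseudotime, motif discovery and GO enrichment; the package consumes
  cluster labels and stage maps as inputs.
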