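---
title: "From qPCR array cards to drug-repurposing candidates: methods and design"
author: "stemscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From qPCR array cards to drug-repurposing candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemscreen)
```

## The problem

Self-renewing, chemotherapy-resistant subpopulations of tumour cells —
cancer stem-like cells (CSCs) — drive progression and relapse in
sarcomas and other solid tumours. A practical route to characterising
them is to grow 3D spheroids from single cells, profile stemness, Wnt
and ABC-transporter transcripts on low-density TaqMan-style qPCR array
cards against matched 2D cultures, and then ask which of the
up-regulated genes can be hit by already-licensed drugs. `stemscreen`
implements that entire computational path: Ct ingestion and
normalisation, moderated differential expression, target
prioritisation, and drug-repurposing candidate scoring — together with
a synthetic-data module that fabricates every input, so the pipeline is
fully testable without any external database or instrument files.

## The Ct model

A cycle-threshold (Ct) value is the PCR cycle at which a target's
fluorescence crosses threshold; low Ct means abundant template. The
package treats Ct as bounded on $(0, 40]$, 40 being the standard
maximum cycle count: wells the instrument reports as "Undetermined"
are stored at Ct = 40 and flagged undetected, which keeps all
downstream arithmetic total while preserving detection status. The
expression tiers follow the conventional cut-offs — highly expressed
below 25 cycles, expressed on $[25, 35]$, not detected above 35. The
published convention leaves the boundary values unassigned ("< 25",
"> 35"); we place both boundaries in the middle tier so the partition
is exhaustive.

**Global-mean normalisation.** To compare targets across the three
card platforms, each target Ct is expressed relative to the global mean
Ct of the analysis panel (all non-control genes):
$\Delta Ct_g = Ct_g - \overline{Ct}_{panel}$. Two properties make this
a safe default for panels of this size: the ΔCt vector sums to zero
over the panel by construction, and adding any constant to every well
leaves ΔCt unchanged (shift invariance). Both are enforced as tests.
Design choices that were genuinely open:

* *Scope of the mean.* Whether the global mean is taken per card or
  jointly across a sample's three platforms is not dictated by the
  arithmetic. The joint mean is the default (`scope = "joint"` in
  `build_dct_matrix()`) because the stated purpose of the
  normalisation is cross-platform comparability; the per-card variant
  is one flag away.
* *Undetected wells.* The global mean includes undetected genes held
  at 40 by default, because the normalisation is defined over the
  whole panel and excluding them would couple the reference to the
  detection pattern; `detected_only = TRUE` restricts the mean for
  users who prefer a detected-only reference.
* *Endogenous controls.* Controls (default `PPIA`, `18S`, `GAPDH`,
  `GUSB`, `HPRT1`; PPIA is the validation housekeeping gene) are
  flagged on ingestion and never enter the panel.

Fold changes for single-assay validation use the comparative Ct
method, $2^{-\Delta\Delta Ct}$, and the self-renewal assay metrics
(spheroid-forming and colony-forming efficiency) are plain percentages
of wells or cells, included so a whole study's quantitative path lives
behind one tested interface. The single-cell seeding density companion
solves $e^{-\lambda}(1+\lambda) = p$ for the Poisson occupancy target
(the conditional reading $P(X{=}1 \mid X{\ge}1)$ is provided as a
separate function; with a 0.9 target the two readings give different
densities and we do not claim either is the original authors' intent).

## Moderated differential expression

With two replicate experiments per condition — the realistic scale for
array-card studies — per-gene variance estimates carry only two
residual degrees of freedom, and an ordinary t-test is hopeless. The
package therefore fits an ordinary two-group linear model per gene and
shrinks the residual variances toward a common prior by empirical
Bayes, exactly the reason moderated methods are standard for this
design. The prior $(d_0, s_0^2)$ is estimated by method of moments on
the log residual variances: with $e_g = \log s_g^2 -
\psi(d/2) + \log(d/2)$,

$$\operatorname{trigamma}(d_0/2) = \operatorname{Var}(e) -
\operatorname{trigamma}(d/2),$$

solved by Newton iteration on the trigamma function, and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the observed
log-variance dispersion does not exceed its sampling noise the prior
degrees of freedom are infinite and the variances are fully pooled (the
arithmetic mean of the per-gene variances); the total degrees of
freedom are capped at the pooled residual degrees of freedom of the
panel. The posterior variance is the usual precision-weighted
combination, and

$$t_g = \frac{\bar x_{gA} - \bar x_{gB}}
{s_{g,post}\sqrt{1/n_A + 1/n_B}}, \qquad
df = d + d_0 .$$

Setting `prior_df = 0` disables shrinkage and provably reduces to the
textbook pooled t-test; the full fit is cross-checked in the test suite
against an independent established implementation of the same
empirical-Bayes model to machine precision. Genes with zero residual
variance are handled entirely by the prior — no division by zero can
occur as long as any gene in the panel carries variance information.

**Significance rule.** A gene is called significant when all three of
the study's conditions hold: Benjamini–Hochberg Q value below 0.1, an
absolute group-mean ΔCt difference above 2 cycles (a four-fold change),
and survival of the Ct detection rule. Published legends state the
detection exclusion two ways — undetected (Ct > 35) in *both*
populations, or undetected in the *2D reference* — so both are
implemented; the stricter "both" rule is the default
(`exclude_mode = "both"`) and the reference-only variant is a flag.
Q values are computed jointly across the three platforms by default
(the per-platform variant is a matter of calling `moderated_de()` per
platform), and sign conventions are fixed so that a positive ΔCt
difference (2D minus 3D) means *increased in 3D spheroids*, because
less Ct is more RNA.

The "mean Ct difference" in the significance rule is evaluated on the
normalised ΔCt scale, matching the quantity on the volcano-plot axis;
the raw-Ct reading is not used.

## Detection-set (Venn) analysis

Comparing two populations' tier maps yields counts of genes not
detected in both, uniquely undetected in each, detected in both and —
within the shared-detected set — highly expressed in both. Percentages
are integer-rounded, half away from zero. Note one subtlety: the share
of highly expressed genes is conventionally quoted relative to the
shared-detected set, not the panel, so the summary reports both
(`shared_high` over the panel and `shared_high_of_detected`).

## Target prioritisation and network structure

The target set is the case-insensitive union of the 3D-increased genes
(source code 2) and a patient-derived CSC gene list supplied as plain
text (source code 1); genes found by both carry `"1,2"`. Interaction
structure among targets enters as an edge list with four evidence
channels (experimental, curated, co-expression, text-mining) — all
channels count toward a target's degree by default, since published
hub statements do not restrict the evidence type; a channel filter is
available. Two notions of a "mutually interacting" core are emitted,
because the looser one is sometimes meant: maximal cliques
(pairwise-complete sets, via maximal-clique enumeration) and connected
components of size at least *k*. The clique finder is validated against
an exhaustive subset-enumeration oracle on all test graphs up to 12
nodes.

## Drug repurposing

Candidate drugs enter from database snapshots (no live queries): a
drug–gene interaction table with publication and data-source counts, a
target–disease association table, a cancer-drug licence list, a
clinical-trial registry extract and a ReDO-style evidence table. The
interaction score for a drug–gene edge is

$$(\text{pub} + \text{src}) \times
\frac{\overline{\text{genes/drug}}}{\text{genes of this drug}} \times
\frac{\overline{\text{drugs/gene}}}{\text{drugs of this gene}},$$

which rewards well-documented, selective interactions and
down-weights promiscuous drugs and heavily drugged genes. The two
averages are taken over the full snapshot by default; restricting them
to the disease-relevant gene slice is exposed as `score_scope =
"slice"` since the original computation's scope is not documented.

Trial aggregation builds per-drug phase, status and cancer-type
histograms with the phase order
Other < Phase 1 < Phase 1/2 < Phase 2 < Phase 2/3 < Phase 3 < Phase 4,
so "Other" is only ever the maximum phase when no numbered phase
exists. Each record contributes exactly once to each histogram axis, so
every axis sums to the trial count — an invariant asserted across the
suite. The support score is the plain count (0–5) of evidence
categories present (in vitro, in vivo, case reports, observational,
trial data); no weighting is applied because none is documented.
Drug-name matching is case-fold-and-trim only — fuzzy matching is
deliberately avoided because silent mismatches are worse than misses.
Single-target drugs are kept in the candidate table by default; the
">1 target" restriction used for licence lookups in some workflows is
a caller-side filter.

## The synthetic-data module

All generators are pure functions of a configuration and one root
seed, split into fixed named streams so adding a generator never
perturbs existing ones. `simulate_ct_cards()` draws one baseline Ct
per gene uniformly (default range 22–34 cycles, the realistic detected
band for these cards), shifts the 3D group by the planted
ΔΔCt effects, adds Gaussian noise (default 0.5 cycles) and clips at 40
with the undetected flag — mirroring ingestion, so simulation and
reading stay consistent. Defaults follow the study design the analysis
targets: a 140-gene panel over three platforms and two replicates per
condition. The interaction, registry, association, ReDO and edge-list
generators fabricate schema-compatible snapshots with the stated degree
structure (per-pair inclusion at `edge_density`, geometric publication
counts, Poisson per-drug trial counts over the registry vocabulary).

What the simulations deliberately do *not* model: primer-efficiency
differences, inter-card batch effects, correlated noise within a
platform, and real database curation biases. Passing tests therefore
demonstrate the correctness of the arithmetic and the operating
characteristics under the stated model, not robustness to those
real-data artefacts.

`make_engineered_bundle()` writes a deterministic reference bundle
whose analysis reproduces the headline structure of the motivating
study: a 21-gene target panel of which exactly 13 (62%) carry at least
one candidate drug, one target (ABCG1) entering through differential
expression alone via a planted 4-cycle decrease in 3D Ct, a POU5F1 hub
of degree 10, a fully interacting 5-gene core (POU5F1, KIT, CAV1,
ITGB1, CD44) and registries whose per-drug trial counts match the
published per-phase histograms. Eight of the 21 panel genes are
synthetic placeholders (the packaged list is named accordingly): the
full published panel is not recoverable from text, and the placeholder
mechanism documents exactly which symbols are real.

## Numerical and operational choices

* Problem sizes in the test and acceptance runs — 1000-gene null
  matrices with 100–200 replicate simulations, 100 random score tables
  up to 20×20, 1000 random cards — were chosen as the smallest sizes at
  which the Monte-Carlo standard errors are far below the margins being
  checked; all complete in seconds.
* BH adjustment delegates to the stock step-up implementation and is
  checked against a brute-force oracle over all permutations of random
  p-vectors; ties inherit the stable input order.
* Tie-breaks are documented everywhere they matter: association-score
  ties resolve alphabetically, clique lists sort by size then
  lexicographically, candidate rows sort licensed-first then
  alphabetically.
* Degenerate inputs fail loudly and early: duplicate (sample,
  platform, gene) triples, unknown condition labels, malformed phase
  literals, self-loop edges, empty normalisation panels and p-values
  outside $[0,1]$ are all hard errors naming the offending record.

## Limitations

The pipeline treats database snapshots as ground truth and performs no
synonym resolution beyond case folding; the moderated model is
two-group only (no multi-factor designs or array weights); and the
engineered bundle demonstrates structural reproduction, not a
re-derivation of database-scale counts, which depend on the versions of
the external snapshots used.
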