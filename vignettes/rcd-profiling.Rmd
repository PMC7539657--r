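---
title: "Profiling regulated cell death gene families across protist proteomes"
author: "rcdProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling regulated cell death gene families across protist proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcdProfiler)
```

## The problem

Regulated cell death (RCD) — apoptosis, autophagic cell death, regulated
necrosis — is usually studied in animals, but its gene families are far
older. Protists exhibit every mitochondrial state from fully aerobic
organelles through anaerobic and hydrogen-producing mitochondria,
hydrogenosomes and mitosomes (mitochondrion-related organelles, MRO), to
complete secondary loss, and lifestyles from parasitic (P) and
(ecto)symbiotic (S) to free-living (F) and transiently multicellular (M).
Comparing RCD gene-family repertoires across such a panel asks whether
cell-death machinery tracks the mitochondrion, the lifestyle, or neither.

`rcdProfiler` implements that comparison as a pipeline over per-species
evidence files: filter homology hits, evaluate Pfam domain-architecture
rules, call each family present or absent per species, optionally reduce
homolog-based calls to ortholog-based calls, assemble the binary
phylogenetic profiles, cluster species, and test group contrasts.

## Family definitions and the rule engine

A gene family is defined by a `GeneFamilyRule`: a category (apoptosis,
autophagy, necrosis), a detection mode, and a boolean formula over Pfam
accessions. Formulas use the field's compact notation: `+` means two domains
must co-occur on the *same protein* (a conserved domain association), `/`
separates alternatives, and `+` binds tighter than `/`. So the HtrA-like
protease formula

```
PF13365 + PF00595 / PF12812 / PF13180 / PF17815 / PF17820
```

reads "(trypsin-like peptidase domain AND PDZ domain) OR any of the
single-domain variants". This precedence is the only reading under which the
single-domain alternatives remain meaningful; the package also accepts each
alternative alone. Conjunctions are evaluated per protein, never across the
proteome: a species with PF00565 on one protein and PF00567 on another does
*not* satisfy the Tudor staphylococcal nuclease (TSN) rule.

Detection modes reflect how the different families are recognisable:

* `domain_only` — presence of a satisfying protein in the domain scan
  (the inhibitor-type apoptosis families such as Bax inhibitor, API5, DAD,
  BIR, NB-ARC/NACHT, and the ATG families);
* `homology_only` — at least one homolog surviving the screen, for families
  with no diagnostic Pfam domain (AIF/AMID, MLKL);
* `combined` — the union (OR) of both channels. Homology search finds
  remote members, domain parsing catches non-homologous carriers; both are
  positive evidence, so the union is the natural combination. Tor is marked
  `combined`: its literature description ("Tor domain homologs") leaves
  open whether the domain or the homology was decisive, and the union
  covers both readings.

Domain E-values are assumed already thresholded by the scanner; an optional
per-call ceiling (`domainEMax`) exists but is off by default. Pfam
accession versions (`.N` suffixes) are stripped everywhere, since family
definitions cite unversioned accessions.

The shipped configuration (`inst/extdata/rcd_families.cfg`, a DCF text file
with one block per family) defines 10 apoptosis, 12 autophagy and
3 regulated-necrosis families; a checksum test pins its content.

## The homology screen

`filterHits()` keeps hits with E-value `< 1e-5`, percent identity `>= 30`
and query coverage `>= 0.80`. Two conventions deserve note:

* **Coverage is computed on the query (bait)**, as
  `(q_end - q_start + 1) / query_length`. For bait-based retrieval this is
  the conventional choice — it demands that the known family member is
  substantially matched, without penalising longer multi-domain subjects.
* **Identity and coverage are inclusive (≥), the E-value cutoff strict
  (<)**, matching the usual "< 1e-5" phrasing of mining thresholds.

`iterateSearch()` runs bait expansion to a fixed point with a round cap
(`maxRounds`, default 3): iterative searches have no natural stopping rule,
and fixed-point-or-cap guarantees termination. The external search tool is
injected as a function; the package never shells out, keeping tests
hermetic.

## Ortholog reduction

Given an ortholog-group membership table (`group_id`, `species_id`,
`protein_id` — e.g. summarised Broccoli output), each family's retrieved
proteins select the **largest containing group**; a species is present iff
it contributes a member to any selected group (for multi-subfamily
categories, at least one ortholog suffices). Three conventions the source
material leaves open are fixed deterministically:

* group size = total protein member count, not species count;
* ties break to the lexicographically smallest group id;
* proteins in no group are ignored (orthology pipelines leave singletons
  unassigned). A family whose retrieved proteins are all unassigned is
  reported as `unassigned`, explicitly distinct from absence.

When groups are built from the retrieved proteins themselves, reduction can
only remove presence, never create it — a property asserted on synthetic
data.

## Profiles, clustering and k selection

Profiles are stored as a `SummarizedExperiment` subclass with binary
`presence` and protein-id `provenance` assays (a cell is 1 iff its
provenance is non-empty — a validity invariant). The species distance is
Euclidean on the 0/1 rows, i.e. the square root of the Hamming count: the
conventional pairing with Ward linkage in the standard clustering stacks.

Ward linkage is implemented directly via the Lance–Williams update on
squared distances,

$$d^2(k, i \cup j) = \frac{(n_i+n_k)\,d^2(i,k) + (n_j+n_k)\,d^2(j,k) - n_k\,d^2(i,j)}{n_i+n_j+n_k},$$

with heights $\sqrt{d^2}$ (the `ward.D2` convention). Binary profiles
produce many exactly tied merge costs, so tie-breaking is fully specified:
among tied pairs, merge the one with the smallest (min creation index, max
creation index), leaves indexed in input order. Ties are detected with a
relative tolerance of `1e-8` — far below the spacing of distinct rational
merge costs at these panel sizes, far above accumulated floating error.
Runs are therefore reproducible bit for bit. The test suite checks the
implementation against a brute-force greedy oracle that recomputes merge
costs from cluster centroids from scratch, and against `hclust(method =
"ward.D2")` on tie-free data.

The number of clusters is chosen by a majority vote of three indices
computed at each candidate k (default 2…min(8, n−1)): Calinski–Harabasz,
mean silhouette width (via the `cluster` package), and the
within-cluster-sum-of-squares elbow (maximum curvature). A 30-index
consensus tool could stand here instead; the three-index vote was chosen as
a deterministic, desk-scale selector whose index table is emitted so users
can inspect disagreement, and no index-level fidelity to any particular
consensus tool is claimed. Ties go to the smallest voted k; a panel of
identical profiles yields k = 1 with a warning.

## Group statistics

`mannWhitneyU()` computes U from rank sums with midranks. The two-tailed
p-value is exact — by enumeration of the tie-free null distribution of U —
whenever `nA*nB <= 400` and the pooled sample is tie-free, and otherwise
uses the normal approximation with tie correction and a 0.5 continuity
correction; the two routes agree within 0.01 at the crossover size, which
the tests assert. Group summaries report mean ± sample SD (denominator
n − 1; the convention is flagged in the output since count data are
sometimes summarised with the population SD). A single-member group reports
SD 0 with an explicit flag rather than NA. P-values are reported, never
used to gate pipeline behaviour.

`groupReport()` reproduces the standard comparison structure of this kind
of survey: diverged (all non-aerobic phenotypes, including the
amitochondriate state) versus aerobic mitochondria; parasitic versus
non-parasitic; transiently multicellular versus free-living.

## The synthetic-data generator

`simConfig()` defaults *are* the study conditions of the 67-protist
reference panel: lifestyle groups P/S/F/M = 17/4/31/15; mitochondrial
phenotypes 51 aerobic, 2 anaerobic, 2 hydrogen-producing, 6 hydrogenosome,
5 mitosome, 1 amitochondriate, with every diverged phenotype assigned to a
parasite (no transiently multicellular protist carries a diverged
mitochondrion). Per-(group, category) presence probabilities are the
reported group mean counts divided by the family count of the category —
apoptosis: P 0.38, S 0.69, F 0.66, M 0.80; autophagy: P 0.38, S 0.74,
F 0.66, M 0.91; necrosis 0 (no necroptosis/pyroptosis homolog was found in
the panel). These values were fixed once from the published group means and
are not tuning knobs.

`simulateTruth()` draws each cell Bernoulli(p) and applies symmetric flip
noise; `emitEvidence()` then fabricates **minimal-sufficient** evidence: one
protein per planted presence carrying the full domain set of one randomly
chosen alternative (domain channel), one tabular hit clearing every screen
threshold with margin (identity 90, coverage 1.0, E 1e-30; homology
channel), and membership in the family's ortholog group — plus per-species
decoy proteins whose single domains are verified by a rule-engine sweep to
satisfy no family (the decoy pool deliberately includes partial conjunction
members such as a lone Tudor domain, exercising the co-occurrence logic).
The generator uses one seeded RNG stream per run (truth at `seed`, evidence
fabrication at `seed + 1`).

What this emulates: planted group effects, noise, decoys, and full
format-level consistency, so the screen → call → reduce → cluster → test
chain is exercised end to end and round-trips the truth exactly at zero
noise. What it does not emulate: real sequence evolution (hits are
fabricated records, not alignments), correlated gene loss along a
phylogeny, paralog inflation, or annotation error structure. Passing tests
therefore demonstrate algorithmic correctness of the pipeline, not that any
biological conclusion transfers to real proteomes — reproducing the real
panel requires the actual proteome downloads and domain-database release,
which is out of scope here by design.

## Problem sizes and numerical choices in the test suite

The suite checks the rule engine against a truth-table oracle (10,000
randomized expression/domain-set pairs), the screen against a naive scan
(10,000 randomized hits plus exact boundary cases), Mann–Whitney exactness
against full enumeration of all 20 splits at n = 3 + 3 and the
normal-approximation agreement at the n = 20 + 20 crossover, Ward linkage
against the brute-force oracle on 50 random binary matrices with up to 7
species, end-to-end round-trips over 25 seeds at 30 species with the full
25-family rule set, planted two-block recovery (probabilities 0.9/0.2, flip
noise 0.05, 15 + 15 species, 100 replicates, adjusted Rand index via
`mclust`), and the null rejection rate of the group comparison over 1000
replicates. These sizes were chosen as the smallest panels at which each
property is sharply testable.

## Known limitations

* Orthology is consumed, never inferred: no tree reconciliation, no
  reciprocal-best-hit fallback. Garbage groups in, garbage reduction out.
* The rule language has no domain order or spacing constraints (none of the
  shipped families needs them).
* The Ward implementation is quadratic per merge and intended for panels of
  tens to a few hundred species, not thousands.
* `homology_only` families are only as good as the bait sets and the
  upstream search; the package deliberately refuses to call them when the
  homology channel was never run (an explicit error, not silent absence).

## Session info

```{r}
sessionInfo()
```
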