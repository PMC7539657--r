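# rcdProfiler

Comparative inventories of regulated cell death (RCD) gene families —
apoptosis, autophagy and regulated necrosis — across protist proteomes.
Protists span every mitochondrial phenotype from fully aerobic organelles
through hydrogenosomes and mitosomes to complete mitochondrial loss, and every
lifestyle from parasitic to transiently multicellular, which makes them the
natural panel for asking whether cell-death gene repertoires track the
mitochondrion, the lifestyle, or neither. `rcdProfiler` is for comparative
genomicists who want that analysis as a tested, reusable R pipeline instead of
a pile of one-off scripts.

## What it computes

1. **Homology screen.** Tabular protein homology hits (the 12-column
   `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
   evalue bitscore` dialect) are filtered by `E < 10⁻⁵`, identity ≥ 30 % and
   query coverage ≥ 0.8, with iterative bait expansion to a fixed point.
2. **Domain-architecture rules.** Each gene family is defined by a boolean
   formula over Pfam accessions in the field's compact notation — `+` is
   co-occurrence on the same protein, `/` is an alternative, `+` binds
   tighter — e.g. the metacaspase substrate TSN is `PF00565 + PF00567`.
   Families are called per species by domain evidence, homology evidence, or
   the union of both, per their configured detection mode. The shipped
   configuration defines 10 apoptosis, 12 autophagy and 3 regulated-necrosis
   families.
3. **Ortholog reduction.** Homolog-based calls are reduced to ortholog-based
   calls using an external ortholog-group table (e.g. Broccoli output): for
   each family the largest group containing a retrieved protein is selected,
   and a species is scored present iff it contributes at least one member.
4. **Profiles, clustering, statistics.** Presence/absence profiles live in a
   `SummarizedExperiment` subclass (families × species). Species are
   clustered with Ward variance-minimisation linkage (Lance–Williams update
   on squared Euclidean distances of the binary profiles, deterministic
   tie-breaks); the cluster number is chosen by a majority vote of
   Calinski–Harabasz, mean silhouette width and the WSS elbow. Group
   contrasts (diverged vs aerobic mitochondria, parasitic vs non-parasitic,
   transiently multicellular vs free-living) are tested with the two-tailed
   Mann–Whitney U test — exact by null enumeration for small tie-free
   samples, tie- and continuity-corrected normal approximation otherwise —
   and reported as mean ± SD per group.
5. **Synthetic data.** A planted-structure generator fabricates internally
   consistent manifests, domain tables, homology hits and ortholog groups
   from per-group presence probabilities, so every stage is testable without
   downloading a single proteome. Its defaults mirror a 67-species protist
   panel (lifestyles P/S/F/M = 17/4/31/15; mitochondrial phenotypes
   51 aerobic / 2 anaerobic / 2 hydrogen-producing / 6 hydrogenosome /
   5 mitosome / 1 amitochondriate).

## Worked example

```r
library(rcdProfiler)

rules <- parseRulesConfig()          # shipped 25-family configuration
rules[["TSN"]]
#> GeneFamilyRule 'TSN' [apoptosis/metacaspase_substrate]
#>   mode: combined
#>   expr: PF00565 + PF00567

cfg <- simConfig(seed = 42)          # default 67-species study panel
bundle <- simulateBundle(cfg, rules) # manifest + hits + domains + orthogroups
prof <- profileBundle(bundle, rules) # screen -> call -> matrix
prof$matrix
#> class: PresenceMatrix
#> dim: 25 67
#> assays(2): presence provenance
#> ...

counts <- categoryCounts(prof$matrix, "apoptosis")
rep <- groupReport(counts, bundle$manifest, "lifestyle")
rep$comparisons$parasitic_vs_nonparasitic
#> GroupComparison: parasitic (n=17, 3.82 +/- 1.85) vs non-parasitic (n=50, 7.00 +/- 1.53)
#>   U = 79.5, two-tailed p = 4.806e-07 (normal_approx)

profiles <- t(presence(prof$matrix)[1:10, ])   # apoptosis families
sel <- selectK(wardLinkage(binaryDistance(profiles)), profiles)
sel$k_best
#> [1] 2
```

Parasites carry about half the apoptosis-gene repertoire of non-parasites in
this panel (3.8 vs 7.0 of 10 families, p ≈ 5·10⁻⁷), and the binary profiles
split the species into two main clusters — the qualitative pattern the
pipeline is designed to detect and quantify.

For file-based runs, `writeEvidenceBundle()` writes the on-disk layout and
`runAll()` executes the whole pipeline over it, emitting presence matrices,
linkage tables, cluster labels, comparisons and a checksummed JSON run
report.

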