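---
title: "Detecting tumor-specific splicing alterations and their epitopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-specific splicing alterations and their epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetope)
```

`splicetope` turns per-sample splice-junction read counts into classified
tumor-specific splicing alterations, reconstructs the protein each one would
produce, and calls candidate MHC-I (or MHC-II) neoepitopes and
splicing-affected self-epitopes. This vignette explains the model behind
each stage, the parameters that matter, the numerical choices, and what the
synthetic test cohort does and does not demonstrate.

## The junction evidence model

The atomic observation is a splice junction: an intron interval supported by
some number of uniquely-mapping spliced reads in each sample. Internally all
coordinates are 0-based half-open; readers and writers convert at the file
boundary (GTF, STAR `SJ.out.tab` and the TSV interfaces are 1-based
inclusive). Gaps shorter than 20 nt are treated as alignment artifacts
(deletions), not introns; the cutoff is a `read_star_junctions()` argument.

Junctions sharing a donor or acceptor coordinate are clustered transitively,
in the style of LeafCutter. Two thresholds shape the clusters:
`min_cluster_reads` (30): clusters with fewer summed reads carry too little
evidence for relative usage to mean anything; and `min_fraction` (0.01):
junctions carrying less than 1% of their cluster's reads are treated as
noise. Pruning is a single pass — after removing sub-fraction members the
totals are recomputed once, and surviving members are kept even if their
recomputed fraction shifts. An iterative refinement would re-prune to a
fixed point; the single pass is deterministic, cheap, and differs only for
clusters sitting exactly at the boundary.

Per-cluster normalization expresses each junction as a fraction of cluster
reads per sample. A sample with zero cluster coverage gets a missing value,
not zero: no coverage is no evidence. Samples missing more than 30% of the
junctions seen in other samples are dropped before any event calling.

A junction is *tumor-specific novel* when (i) it is not an annotated intron,
(ii) at least one tumor sample gives it ≥ `novel_min_reads` (10) reads, and
(iii) it is absent from the normal-junction compendium and shows zero reads
in matched normal samples. Compendium membership is strand-agnostic
`(chrom, start, end)` because compendia built from unstranded libraries
carry no reliable strand; this errs on the conservative side (a normal
junction on the opposite strand still disqualifies). The 10-read threshold
is applied after cluster pruning, so a junction must survive the cluster
context first.

## Event classification

Four mutually exclusive event types are called per tumor sample:

* **Aberrant splice site** — exactly one splice site annotated; the novel
  site must fall inside the host gene's span.
* **Neoskipping** — both sites are annotated exon boundaries of one gene,
  the junction is not an annotated intron, and at least one annotated exon
  lies strictly inside it.
* **De novo exonization** — two junctions splicing from the annotated donor
  and to the annotated acceptor of the same annotated intron define a new
  internal exon. The exon must be ≤ `max_exon_len` (500) nt, must show the
  canonical context on the coding strand (AG immediately upstream, GT
  immediately downstream — the acceptor/donor dinucleotides of the new
  introns), and each flanking junction needs strictly more than
  `min_site_reads` (5) reads. For minus-strand genes the genomic lookup is
  reverse-complemented. Because each flanking junction individually looks
  like an aberrant splice site (one annotated, one novel site), exonization
  pairing runs first and consumes its junctions; this is the only ordering
  that keeps the four types exclusive per anchor. Exonization flanks are
  validated at their own > 5-read rule rather than the 10-read novelty
  threshold — the pair of consistent junctions is itself the corroborating
  evidence.
* **Intron retention** — called from precomputed intron-body and
  flanking-exon read counts: body/flank ratio ≥ `ir_min_ratio` (0.1) and
  body ≥ `ir_min_body_reads` (10). This coverage-ratio caller is a
  deliberate redesign of the published external KMA/Kallisto quantification
  route: the package consumes coverage tables rather than wrapping two
  external tools, and the downstream logic is unchanged. Two subtractions
  keep calls tumor-specific: introns that are annotated retained introns
  (fully exonic in another transcript of the same gene — the
  `enumerate_annotated_ri()` exclusion set, equivalent to removing events
  already present in the annotation) and introns called retained in any
  normal sample by the same thresholds. A zero flank with positive body
  yields an infinite ratio and is emitted with a message rather than
  silently dropped.

### The empirical read-support test

Genes with globally disturbed pre-mRNA processing produce many weakly
supported oddities. To require that an event stands out *within its own
locus*, its support is compared with `n_random` (100) values drawn with
replacement from a same-gene background pool: other junctions' supports for
splice-site and neoskipping events, read counts of genic regions of similar
length (± 20%) for exonizations, other introns' body counts for retention.
The one-sided add-one p-value is

$$p = \frac{1 + \#\{\text{draws} \ge \text{observed}\}}{1 + n_\text{random}}$$

so the smallest attainable value is 1/101 ≈ 0.0099 and an event is kept at
`alpha` = 0.05 only when at most 4 of 100 draws reach its support. The
± 20% length tolerance for exonization backgrounds, and the use of raw
supporting reads (not cluster fractions) as the statistic, are choices the
underlying description leaves open; both are exposed in the interfaces. An
event whose background pool is empty cannot be tested and is retained
flagged `untested` — dropping it would silently punish genes with sparse
annotation.

## From event to protein

Each gene's reference transcript is the one with the largest mean TPM among
transcripts exceeding `tpm_min` (1 TPM), with the mean taken over the
control/normal samples when the cohort has them (tumor expression should not
pick the reference isoform) and ties broken by lexicographically smallest
transcript id for determinism. Its protein is the translated annotated CDS,
or the longest ORF when no CDS is annotated; genes whose chosen transcript
yields no protein of ≥ `min_orf_aa` (25) residues are excluded from the
proteome and logged — peptides of an 8–11-mer pipeline need some context,
and shorter products are dominated by noise.

`apply_event()` rewrites the reference exon chain: boundary moved to the
novel site (aberrant splice site), interior exons removed (neoskipping), new
exon inserted (exonization), intron fused into its flanking exons
(retention). Events whose anchors do not fit the reference exon chain (for
example a novel site falling into no intron of the reference isoform) are
skipped with a logged incompatibility rather than guessed at.

The altered ORF starts at the reference start codon's position projected
onto the altered transcript. If the event deleted that codon, the closest
downstream ATG — in transcript coordinates, the only frame-consistent
space — that reaches an in-frame stop is used and the ORF is flagged
`start_rescued`. Without an annotated CDS the longest ATG→stop frame wins,
ties to the 5'-most start. ORFs without an in-frame stop are rejected.
Codons containing N translate to `X`, and peptides containing `X` are never
called downstream.

The NMD rule discards an altered transcript when its stop codon lies more
than `nmd_window` (50) nt upstream of a downstream exon–exon junction,
measured from the base after the stop codon's last base; a distance of
exactly 50 nt is kept ("further than"). Events touching only the UTR
(footprint disjoint from the genomic CDS span) are flagged `utr_only` and
produce no altered protein; events straddling the CDS boundary count as
coding-affecting.

## Epitope calculus

Candidate peptides are all distinct 8–11-mers (`kmin`/`kmax`; 15-mers for
MHC-II via the same code path). Peptides shared by the reference and
altered protein are discarded. A **splicing-neoepitope** is an
altered-protein peptide absent from the entire reference proteome (a hashed
8–11-mer index gives constant-time membership) with predicted affinity ≤
`threshold_nm` (500 nM; 300 nM reproduces the stricter sensitivity setting)
for at least one of the sample's HLA alleles. A **self-epitope** is a
reference-protein binder whose encoding is lost in the altered protein.
When the altered protein is absent because of NMD or ORF loss, self calls
are restricted to reference peptides overlapping the event's footprint on
the reference protein (`self_scope = "event"`): NMD of one isoform does not
deplete peptides encoded far from the lesion, since the unaffected allele
and isoforms still express them. `self_scope = "protein"` gives the more
aggressive whole-protein reading.

Affinities come from a NetMHC-style tabular file
(`read_netmhc_output()` auto-detects the common header dialects) or from
`predict_affinity_surrogate()`: a pure function mapping each peptide ×
allele to `50000^(1-s)` nM, where `s` is an anchor-weighted (positions 2 and
C-terminus, four-fold weight) mean of fixed per-allele residue-position
weights shipped as a plain-text data file. The surrogate has **no
predictive value** — its only contract is determinism, a realistic dynamic
range (1–50000 nM, a few percent of random peptides under 500 nM), and
allele-dependence, which is what the set-algebra and threshold logic need
for testing.

## Statistical post-processing

* **MS validation.** Matching against an MS-identified peptide list is
  exact string intersection, optionally after folding I to L (isobaric in
  MS). The randomized validation test draws 1000 peptides from the
  high-affinity pool and 1000 from the full candidate pool, counts MS
  matches in each, repeats 100 times, and compares the two count
  distributions with the two-sample Kolmogorov–Smirnov statistic. The
  p-value is computed by label permutation (999 permutations) rather than
  the asymptotic KS distribution: the two samples are 100 small integers
  with heavy ties, where the asymptotic p is several-fold conservative,
  while the permutation null is exact under ties. Pools smaller than the
  draw size are sampled with replacement, with a message.
* **Affinity comparisons** between groups (e.g. therapy responders vs
  non-responders) use the standard two-sample `ks.test` — affinities are
  effectively continuous — and export cumulative curves for plotting.
* **Self-epitope proportions** are |SELF| / (|SELF| + |NEO|) per stratum,
  reported as missing when a stratum has no calls.
* **Biomarker enrichment** is a two-sided Fisher exact test per gene set
  (2 × 2: epitope-bearing genes × set membership within the tested
  universe) with Benjamini–Hochberg correction across sets; one-sided
  testing is available by argument.

## The synthetic cohort

`generate_fixtures()` builds a deterministic cohort from a seed: genes of
3–8 exons (60–300 nt) with GT..AG introns (≥ 80 nt, one long intron per
gene so exonizations have room), annotated CDSs of ≥ 60 codons, both
strands, one tumor and three normal samples. Every fifth gene carries a
second lowly-expressed transcript retaining an intron, seeding the
annotated-RI exclusion set. Planted events exceed every threshold with
margin — novel junctions at 12–40 reads on an annotated-junction baseline
of 4–9 (tumor) / 10–16 (normal) reads, exonization sites at 8–20 reads,
retention bodies at 30–60 reads over ~100× flanks (ratio ≥ 0.3) — while
decoys violate a single rule each: a 501-nt exonization, 5-read splice
sites, a compendium-member junction, a 9-read junction, a sub-ratio
retention, and a retention matching the annotated-RI set. Backgrounds
(same-gene junction counts, length-matched genic regions, other intron
bodies) are planted low so the empirical test passes planted events and
stays meaningful.

The default scales used by the tests and the acceptance script — 110 genes,
20 events per type for recovery checks, 1000-draw × 100-repetition
validation runs over 200 seeds, BH on 1000 p-values × 200 replicates — keep
a full run in tens of seconds on one core while leaving every threshold
exercised on both sides.

What passing these tests shows: the set algebra, threshold boundaries,
coordinate arithmetic, strand handling, ORF reconstruction and statistical
calibration are correct. What it does not show: behavior on real RNA-seq —
the generator plants clean junction counts with no mapping ambiguity, no
overlapping genes, no paralog-induced false novelty, uniform coverage, and
an affinity surrogate instead of a trained predictor. Recall on planted
events is a software property, not an estimate of sensitivity on tumors.

## Known limitations

Cross-gene junctions (candidate fusions), RNA editing, quantitative PSI
estimation, uORFs, selenocysteine readthrough and spectrum-level MS search
are out of scope. The intron-retention caller depends on the quality of the
supplied coverage table. Only the reference isoform per gene is edited, so
events compatible only with a minor isoform are skipped (and logged); genes
whose reference transcript falls below 1 TPM in controls are invisible to
the ORF stages by design.
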