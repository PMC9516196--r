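---
title: "Methods: pooled-F2 SNP-index mapping and co-regulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-F2 SNP-index mapping and co-regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the simulator does and does not emulate, and
the design choices made where more than one defensible option existed. No
empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` compute.

## The mapping model

A recessive mutant is crossed to its progenitor; F1 plants are heterozygous
at the causal locus and at every mutagen-induced background SNP of the line.
Among F2 individuals selected for the recessive phenotype, both gametes carry
the causal allele. For a locus at recombination fraction $r$ from the causal
site, each selected gamete carries the linked mutant allele with probability
$1 - r$, so the expected pooled allele frequency — the SNP index — is

$$\mathbb{E}[\text{index}] = 1 - r,$$

exactly 1 at the causal locus, decaying along the chromosome, and $1/2$ at
unlinked loci (each gamete transmits the mutant allele of an unlinked SNP
with probability $1/2$ regardless of selection). Mapping is therefore a
search for the genomic region where the index approaches 1.

### The forward simulator

* **Genome.** `default_genome()` has twelve chromosomes with approximately
  the rice reference-assembly sizes (~373 Mb) and a uniform genetic map of
  4 cM/Mb, close to the rice genome-wide average. No nucleotide sequence is
  materialized at this scale; small annotation fixtures attach explicit
  sequence.
* **Mutagenesis.** Background SNPs are uniform over physical coordinates;
  substitution classes are drawn from a spectrum that defaults to 0.85
  probability of G:C→A:T transitions, the class dominating sodium-azide and
  EMS mutagenesis in plants (both causal changes modelled in the annotation
  fixtures are of this class), the remainder spread evenly over the five
  other classes. Position collisions are redrawn, never dropped, so the
  background count is exact. Because no shared sequence exists at genome
  scale, two *independently* simulated lines could claim different reference
  bases at a coincidentally shared position — impossible against a real
  reference — so `simulate_mutagenesis(avoid = )` draws a second line's
  positions disjoint from the first (conditioning on the no-collision event,
  which has negligible probability mass at these densities).
* **Recombination.** Haldane model: crossover counts are Poisson in the
  chromosome's genetic length, positions uniform in genetic distance, no
  interference; $r = \tfrac12(1 - e^{-2d})$ for distance $d$ in Morgans.
  The data modelled here give no information about interference, and the
  Haldane model is the standard minimal choice.
* **Selection.** The recessive phenotype is taken as fully penetrant:
  `mutant_phenotype` selection keeps exactly the individuals homozygous for
  the causal alt allele, as implied by a 1:3 F2 segregation. Individuals are
  drawn until the pool is filled, with a hard cap of 100× the pool size.
* **Reads.** Per-site depth is Poisson with the nominal coverage; alt reads
  are Binomial with success probability $f(1-e) + (1-f)e$, where $f$ is the
  true pooled frequency and $e$ the per-base specific-allele miscall rate
  (default $10^{-3}$, a realistic post-filter rate). Mapping and base
  qualities are drawn above the default filter thresholds; the filter's
  behaviour is tested with adversarial records instead.
* **Wild-type and cross-pool comparison sets.** Variants fixed in both
  parents (cultivar-vs-reference polymorphisms) are homozygous in every F2,
  so they appear at index ~1 genome-wide — exactly the false candidates the
  wild-type exclusion removes. The wild-type pool emits records only at its
  own variant sites, as a variant caller would; it does not emit error piles
  at other loci.

What the simulator does **not** emulate: read-level artefacts (no FASTQ,
alignment or calling), error-motif structure, segregation distortion,
phenotyping error (incomplete penetrance or misclassification), and the
M1/M2 propagation of the mutagenized generations. Passing tests therefore
demonstrate correctness of the pipeline's statistics under a clean
generative model, not robustness to misclassified phenotypes or systematic
calling artefacts in real data.

### Mapping parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_mapping_quality` | 30 | phred | standard high-quality read filter |
| `min_base_quality` | 20 | phred | standard base filter |
| `min_total_depth` | 5 | reads | indices from <5 reads are too unstable to plot or scan |
| `presence_min_alt_reads` | 2 | reads | read-support presence is robust at ~20×; a single read is too error-prone to declare sharing |
| `window_size` / `step` | 1 Mb / 100 kb | bp | at ~5 induced SNPs/Mb a 1 Mb window averages a handful of sites; the step gives 10× overlap for smooth peaks |
| `min_sites_per_window` | 2 | sites | a one-site mean is not a mean |
| `index_threshold` | 0.9 | index | operationalises "close to 1" while tolerating read noise at 20× |
| `min_sites` (region) | 3 | sites | a candidate region needs independent support |
| `merge_gap` | 2 | windows | short sub-threshold dips inside a decay peak do not split it |

Windows are half-open `[start, start + window)` internally and reported
1-based inclusive; ties between equal-scoring regions break by genomic
order. One refinement matters in sparse data: windows with fewer than
`min_sites_per_window` sites are *neutral* — they neither qualify nor break
a run — because absence of sites is absence of evidence; only a window that
actually scans below the threshold separates two peaks. Without this rule a
causal SNP sitting in a locally sparse stretch can be split out of its own
peak region.

### Recovering the genetic map from index decay

Inverting $r = 1 - \text{index}$ through the Haldane map gives a per-site
genetic distance $\hat d = -\tfrac12\log(1 - 2\hat r)$; regressing $\hat d$
(in cM) through the origin on physical distance (Mb) estimates the map rate.
Two numerical points:

* Sites with $r$ near $1/2$ are excluded (`max_r = 0.35`) because the
  inverse map degenerates there. A naive cut on the *estimated* $\hat r$
  preferentially admits boundary sites whose noise pushed them downward,
  biasing the recovered rate low by a few percent; the implementation
  therefore refits with a second-stage cut based on the $r$ *predicted*
  from distance and the first-stage rate, which is independent of each
  site's own noise.
* Within one pool all sites on a chromosome share gametes, so a single
  realization has strongly correlated errors. The estimator's *bias* is
  meaningful only as an average over independent replicates; the acceptance
  checks average 15 replicate estimates (each from 10 pools of 76
  individuals at 100×) and find the mean within a few percent of the
  simulated 4 cM/Mb.

## Codon-effect annotation

Gene models carry genomic CDS segments (1-based inclusive, total length
divisible by 3) and optional protein domains in amino-acid coordinates. A
variant inside a CDS is mapped to its coding-sequence position (strand
aware: minus-strand alleles are complemented and codons read 5′→3′ on the
coding strand), its codon is rebuilt from the reference, and reference and
alternate codons are translated with the standard nuclear genetic code.
Categories partition all CDS point substitutions: synonymous, missense,
nonsense (gained stop); loss of the annotated stop is reported as missense
with a `stop_loss` flag, the simplest complete rule for a case the analyses
here never meet. "Splice-adjacent" is defined as within 2 bp of an internal
CDS boundary on the intron side — a testable convention, reported but never
causal in these analyses. Domain hits use inclusive amino-acid bounds; the
first matching domain wins (domains in these models do not overlap).

## Segregation testing

For observed class counts $O_i$ against expected $E_i$ from a Mendelian
ratio, the statistic is $\sum_i \max(|O_i - E_i| - c,\, 0)^2 / E_i$ with
$c = \tfrac12$ under the Yates continuity correction and $c = 0$ without.
The clamp at zero prevents a deviation smaller than the correction from
contributing. For a two-class test the corrected form is the default — for
the worked 29:91 vs 1:3 case the corrected statistic is 0.011 and the
uncorrected one 0.044, and only the corrected form matches the value such
analyses conventionally report — but both forms are exposed. Expected
counts below 5 trigger a warning, not an error.

## DEG thresholds, overlap and clustering

A gene is a DEG when $P \le 0.05$ and $|\log_2 \mathrm{FC}| \ge 1$, both
bounds inclusive. The fold-change bound is read two-sided: analyses of this
kind report both up- and downregulated DEG counts, which only exist under
the two-sided reading; direction is the sign of the fold change (exactly
zero cannot pass the filter). Overlap statistics are exact set algebra on
gene identifiers; percentages are rounded half away from zero to one
decimal, matching the conventional printed style (base R's
round-half-to-even would turn 92.45 into 92.4). Clustering uses complete
linkage on Euclidean distances — the defaults of the standard heat-map
workflow — on both genes and contrasts; zero-variance columns are fine,
missing values are an error unless zero-imputation is requested explicitly.

### Constructed DEG tables

The DEG simulator is constructive, not sampled: every gene receives a joint
direction profile across the contrasts, and per-profile counts are realized
exactly, so planted intersection sizes and concordance fractions are
deterministic. `coregulation_profiles()` is the canonical three-contrast
structure (two single mutants of interacting activators plus their double):
thirteen profile cells chosen so that all the overlap marginals of interest
are hit exactly — 1,128/217 down/up in one single, 866/348 in the other,
1,853/213 in the double, 757 shared between the singles of which 729
concordant and 666 down-down, 654 of those also down in the double, and
1,197 of the 1,328 union-downregulated genes regulated in the double. Cells
not pinned by any of those numbers (the double-mutant direction of
DEGs private to one single mutant) are closed with the least-structured
choice, "none". DEG p-values are uniform on (0, 0.05], non-DEG p-values
uniform on (0, 1); DEG fold changes are sign-consistent with magnitude
$1 + \mathrm{Exp}(1.2)$, non-DEG magnitudes below 1 — so the filter recovers
the planted sets exactly and the null p-distribution is uniform.

## Enrichment with permutation correction

Each term is tested against the expressed-gene background (genes with at
least 2 read counts) with both one-sided hypergeometric tails; the smaller
tail is reported with its direction (enrichment or depletion), ties going
to enrichment. A term with no background genes is degenerate: $p = 1$, no
direction. The multiple-testing correction is empirical: `n_perm` (default
1,000) random gene sets of the observed DEG size are drawn uniformly
without replacement from the background, every term's Fisher p is
recomputed, and

$$P_{\text{corr}} = \frac{1 + \#\{\text{perm } p \le \text{obs } p\}}{1 + n_{\text{perm}}},$$

the add-one form that never returns zero and is bounded below by
$1/(n_{\text{perm}}+1)$. "At least as extreme" is read **per term** — each
term's permuted p compared with its own observed p — rather than as a
global count of significant terms per permutation; the per-term reading is
the most direct one and is what the implementation provides. Permutations
resample gene labels at fixed set size, preserving the annotation
structure. Significance uses the strict inequality
$P_{\text{corr}} < 0.05$.

In the annotation simulator, a planted fold of exactly 1 means "no
planting" (the term is a uniform subset, so null calibration holds), while
any other fold realizes the expected overlap
$\mathrm{round}(\text{fold} \times \text{size} \times |D|/N)$ exactly,
making power checks reproducible rather than themselves noisy.

## Problem sizes used by the tests and the acceptance script

The simulation-backed checks run at the sizes of the modelled study design:
F2 pools of 76 (and 18) individuals at 20× with 2,000 background SNPs, 100
mapping replicates; map-law checks at 100× over 15 replicate lines with 10
pools each; enrichment calibration with a 5,000-gene background, 200 DEGs,
100 terms, 1,000 permutations and 20 replicates; the codon oracle is
exhaustive (64 codons × 9 substitutions). These sizes make the full suite
and the acceptance script each run in on the order of a minute on one CPU.

## Known limitations

* No confidence band on the SNP index (the original MutMap interval is not
  part of this pipeline); peak calling is threshold-based.
* Single-nucleotide substitutions only: no indels, MNVs, isoform
  resolution, or UTR/promoter effect prediction.
* Flat annotation maps: no ontology-graph propagation of gene-term links,
  matching the curated flat collections such analyses use.
* The permutation null assumes exchangeability of genes within the
  background; expression-level-dependent annotation bias is not modelled.
* The genetic map is uniform within chromosomes; real recombination
  landscapes (centromeric suppression, hot spots) will distort the
  index-decay-to-distance relationship locally.
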