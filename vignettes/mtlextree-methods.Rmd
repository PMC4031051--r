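---
title: "Lexical haplotype-tree association for mtDNA: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical haplotype-tree association for mtDNA: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlextree)
```

# The problem

Human mtDNA is maternally inherited, effectively haploid, and essentially
free of intermolecular recombination. Every polymorphism therefore travels
on a fixed genealogical background: carriers of a derived allele are (to a
good approximation) a clade, and disease signals can live at any level of
the nesting — a single recent variant, a subhaplogroup, or a deep macro-
lineage. `mtlextree` tests for case-control association at *all* levels at
once, without committing to a published haplogroup nomenclature, and wraps
the data hygiene such a test needs on array genotypes.

# The lexical tree test

## Tree construction

Input is an $n \times m$ haploid genotype table over $\{0, 1\}$
(0 = reference allele on the rCRS, NC_012920; 1 = alternate), with **no
missing calls** — the QC cascade below guarantees this. SNPs are ordered by
decreasing minor allele frequency (MAF, folded to $[0, 0.5]$); ties are
broken by ascending rCRS position so the order is reproducible. Starting
from a root holding everyone, each SNP in turn splits every current leaf
into a reference ("wild-type", left) child and a mutant (right) child,
*provided both are non-empty*; otherwise the leaf's haplotype prefix extends
silently. Consequences used throughout:

* leaves are in bijection with the distinct observed haplotypes;
* every node's member set differs from its parent's (nodes arise only from
  true splits), so no membership-identical chains exist and no partition is
  ever scored twice;
* children partition their parent, and case + control counts are conserved
  at every node (a tested invariant).

## Node statistic

For each non-root node the package computes the 1-df Pearson chi-square of
the $2 \times 2$ table (in-node vs out-of-node) $\times$ (case vs control),
without continuity correction, defined as 0 whenever a margin is zero. The
statistic choice is a design decision of this package: it is the natural
count-based statistic for case-control membership, matches the single-
variant allelic test used elsewhere in the pipeline, and is cheap enough to
vectorise over nodes $\times$ permutations. `node_statistics()` is a plain
data-frame interface, so alternative node scores can be computed from the
same counts if a different sensitivity profile is wanted.

Direction (risk/protective) is the sign of the cross-product
$a d - b c$; the two children of the root split are exact complements and
carry equal statistics with opposite directions, which is correct and
intentional.

## Whole-tree statistic and permutation null

$S$ is the sum of the five largest node statistics over a set of mutually
non-nested nodes (an antichain), selected **greedily**: visit statistics in
decreasing order (ties: shallower depth, then smaller node id) and accept a
node iff it is neither ancestor nor descendant of an accepted one. The
greedy rule is the construction implemented, deliberately, rather than a
maximum-weight-antichain optimisation; the greedy set is the canonical
reading of "the five largest values that are not nested", and it is what the
permutation null re-applies, so observed and null statistics are always
computed by the same rule. (An exact optimiser would change both sides of
the comparison together; we judged the added complexity unjustified.)

Significance comes from uniform permutation of the case/control labels with
the topology and memberships fixed; per permutation the node counts are
recomputed by an indicator-matrix product and $S$ re-derived. The p-value
uses the add-one estimator $p = (1 + \#\{S_{perm} \ge S_{obs}\}) /
(1 + n_{perm})$, which is valid for finite permutation counts and never
reports zero; its floor is $1/(n_{perm}+1)$.

# Quality control

Two cascades, both strictly ordered, both emitting a per-stage removal
ledger whose row sums must reconcile with the final table (a tested
invariant).

**Lexical cascade** (`lextree_qc`), defaults in parentheses:

1. drop SNPs with call rate < `snp_call_rate_min` (0.95) **or**
   MAF < `snp_maf_min` (0.005);
2. drop the `worst_individual_fraction` (0.02) of individuals with the most
   missing sites;
3. drop the `worst_snp_fraction` (0.50) of SNPs with the most missing
   samples;
4. drop individuals with any missing call on the surviving SNPs;
5. drop individuals whose complete haplotype is carried by fewer than
   `rare_haplotype_min_count` (5) individuals or by no control.

Stages 2 and 3 remove a *fixed fraction*, rounded down, even from complete
data — stage 3 in particular always halves the SNP panel. Ties in
missingness are broken by sample-id order (stage 2) and ascending position
(stage 3): with no missingness the trimmed SNPs are simply the lowest-
positioned half. These tie-breaks exist purely for reproducibility; analyses
of data with real missingness are driven by the counts, not the tie-break.
A consequence worth knowing when simulating: a planted variant at a low rCRS
position can be discarded by the stage-3 tie-break in a missingness-free
cohort, so the package's own planted-effect fixtures put the effect variant
high on the genome (m.15218-style).

**Primary cascade** (`primary_qc`): (1) drop missing phenotypes (the PLINK
`-9` code); (2) drop SNPs with missingness > `snp_missing_max` (0.1);
(3) drop individuals with missingness > `individual_missing_max` (0.1),
computed on the stage-2 survivors; (4) drop non-European lineages;
(5) drop SNPs with MAF < `primary_snp_maf_min` (1e-5, i.e. essentially the
monomorphic ones). Missingness denominators are post-phenotype-pruning
throughout; the MAF stage is part of the cascade for every cohort (it can be
neutralised by setting the threshold to 0 if a user wants it applied only to
merged controls).

**European filter.** European (macrohaplogroup-N background) mtDNAs are
identified by the diagnostic triplet m.8701A, m.8540T, m.10873T. An
individual is kept only if **every testable** diagnostic position (genotyped
on the array, called for that individual) shows the European allele; the
triplet jointly defines the lineage background, so one non-European allele
suffices for removal, while an untestable position is never held against an
individual. If none of the three positions is genotyped the filter warns and
passes the table through unchanged. The same keep-if-all-European rule is
applied to sequences in the panel module, where a position beyond a
truncated sequence's end counts as untestable.

**Control merging and differential missingness.** Two control cohorts are
merged after a per-SNP haploid chi-square concordance check (removal at
P < `control_discordance_p`, default 0.05, strict inequality — a threshold
of 0 removes nothing). Case/control differential missingness uses the same
2×2 machinery on missing/called status, removing at P < `diff_missing_p`
(1e-4); a SNP with no missing calls anywhere has a zero margin and thus
statistic 0 — kept, by convention.

# Single-variant association and power

`allelic_test` counts one allele per individual (haploid counting — a
deliberate divergence from diploid-doubling defaults of general-purpose
tools), computes the 2×2 chi-square and asymptotic p, and the odds ratio
with the Haldane–Anscombe 0.5 correction applied only when a cell is zero.
Monomorphic SNPs are emitted with NA statistic/OR and a flag rather than
dropped silently. `risk_direction_tally` splits discovery-threshold
survivors by OR direction and reports the two-sided **exact binomial** p
against a 50:50 split; for a 61-vs-38 split that test gives p ≈ 0.027 — an
order of magnitude weaker than what cruder approximations can suggest, which
is why the exact test is the one reported.

`power_calc` solves the haploid multiplicative model
$K = pK_1 + (1-p)K_0$, $K_1/K_0 = R$ for the penetrances, derives the
retrospective case/control allele frequencies by Bayes, and evaluates the
1-df noncentral chi-square power. With $R = 1$ it returns exactly
$\alpha$. Limitation: published power figures for mtDNA array studies are
typically produced by diploid genotypic calculators whose auxiliary
assumptions (allele counting, marker/risk-locus distinction, per-cohort
$\alpha$) are rarely fully stated; at low MAF the haploid single-allele
model here gives materially lower power than such figures, so cross-tool
comparisons should fix the model first. The implementation is validated
instead against a direct retrospective simulation oracle (analytic vs
simulated power agree within 0.02 at the reference fixture
$K=0.01, p=0.2, R=2, 500/500$).

# The synthetic-data generator

The generator exists because real mtDNA case-control array data of this
kind is access-controlled; it emulates the *statistical structure* the
analysis assumes, not mtDNA mutational history.

* **Clades** form a forest; each `clade_def` has defining variants (disjoint
  from its ancestors'), a frequency — interpreted as *conditional on parent
  membership*, with siblings summing to ≤ 1 and the remainder staying on the
  parent background — and an odds ratio.
* **Disease model**: logistic on clade membership,
  $P(\text{case}) = \text{logit}^{-1}(\log(\text{baseline\_odds}) +
  \sum_{\text{lineage}} \log OR)$.
* **Retrospective sampling**: individuals are drawn until exactly
  `n_cases` cases and `n_controls` controls accrue (draw cap
  `1000 × (n_cases + n_controls)`, then an informative abort). Under a rare
  disease the planted case-carrier frequency obeys
  $f R / (1 - f + f R)$ — a tested law.
* **Missingness**: per-call probability
  $1 - (1 - s_{\text{snp}})(1 - s_{\text{ind}})$; phenotypes masked at their
  own rate. Because masking applies to already-ascertained rows, observed
  case + control + missing-phenotype counts always sum to the rows written.
* **Panels**: equal-length sequences from a deterministic *synthetic*
  reference (an ACGT cycle with the three diagnostic bases pinned European —
  it is not the real rCRS sequence and never claims to be), plus optional
  truncation, non-European contamination (m.8701G) and Poisson private
  variants for a realistic rare-variant MAF spectrum (default 0 so that a
  clade-free panel is exactly the reference).

Everything is deterministic given the seed; identical configs give
byte-identical PED/MAP files and study reports.

**What passing tests do and do not show.** The generator plants clean
binary haplotypes: no homoplasy, no intensity-level artefacts, no platform-
specific missingness structure, no population stratification beyond the
planted clades, and MAFs that are exact Bernoulli parameters rather than
estimates. Calibration and recovery results on simulated cohorts therefore
validate the *machinery* (statistics, ordering, permutation law, QC
arithmetic) — they do not certify power or error rates on any particular
real platform.

# Numerical and interface choices

* 2×2 chi-square: closed form $N(ad-bc)^2/(r_1 r_2 c_1 c_2)$, computed in
  double precision (counts coerced from integer to avoid overflow), defined
  0 at zero margins; agrees with `stats::chisq.test(correct = FALSE)` to
  1e-10 relative (tested on 1,000 random tables).
* PED/MAP: mtDNA written as chromosome "26"; haploid calls as homozygous
  diploid; heterozygous calls on load are set missing and counted. PED/MAP
  carries no allele-polarity channel, so `load_plink` accepts an explicit
  ref/alt map and otherwise falls back to first-seen-as-reference.
* BED annotation input (0-based half-open) is converted to 1-based inclusive
  rCRS internally; the conversion is tested at both interval edges.
* Problem sizes in the test suite — 500 null cohorts of 200+200 at 999
  permutations for calibration, 200 replicates of 500+500 for planted-effect
  recovery, $10^4$ replicates for the power oracle — were chosen to put
  Monte-Carlo error well inside the asserted bounds while keeping the suite
  quick to run routinely.

# Known limitations

* Multi-allelic SNPs are rejected (genotypes) or excluded with a flag
  (sequence panels); mtDNA heteroplasmy is out of scope.
* The permutation test assumes exchangeable labels — residual population
  structure within cases or controls is not corrected for (no PCA
  stratification adjustment is provided).
* The greedy antichain is not guaranteed to be the maximum-weight antichain;
  see the design discussion above.
* Sequence panels must arrive pre-aligned to reference length; alignment
  itself is a routine upstream step and intentionally not reimplemented.
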