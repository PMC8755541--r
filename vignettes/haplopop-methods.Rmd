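---
title: "Methods and models behind haplopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind haplopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopop)
```

haplopop is a toolkit for the population genomics of highly heterozygous,
clonally propagated crops — the lychee situation, where a single cultivar
carries two deeply diverged haplotype genomes inherited from two wild source
populations, cultivar groups differ in which haplotype they resemble, and
the cultivation history is a web of first- to third-degree relatives rather
than a random-mating population. This vignette explains the statistical
models the package implements, the choices made where the methodology was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Variant filtering

Hard filtering follows the GATK `VariantFiltration` idiom: a site fails when
*any* predicate fires. Two presets ship with the package. The `population`
preset (`DP < 300 || DP > 3000 || QD < 2.0 || FS > 60.0 || MQ < 40.0 ||
MQRankSum < -12.5 || ReadPosRankSum < -8.0`) is the joint-calling filter for
a resequencing panel; the `phasing` preset (`QD < 2.0 || MQ < 26.0 ||
FS > 100.0 || SOR > 5.0 || MQRankSum < -7.5 || ReadPosRankSum < -8.0`) is
the stricter-MQ single-accession filter used ahead of haplotype phasing.
Sites missing an annotation named by a rule are retained with a warning in
the default lenient mode — the common behavior of hard-filter tools — and
rejected in strict mode. Filtering is applied before biallelic-SNP
selection; the missingness filter is strict ("over 80%" means a
called-genotype fraction that *exceeds* 0.8, so 8 of 10 does not survive).

Coordinates are 1-based and closed throughout the package, the
IRanges/Bioconductor convention, so no conversion happens at the VCF/GFF3
boundary; BED depth input is converted from 0-based half-open on read.

## Diversity statistics

Sitewise nucleotide diversity is the unbiased pairwise estimator over the
called alleles at a site, $\pi = \sum_{a<b} n_a n_b / \binom{n}{2}$, with
missing genotypes excluded site-wise and indel sites skipped (the diversity
statistics are SNP statistics). Windowed $\pi$ divides the summed sitewise
values by the *full* window length, so monomorphic and uncalled positions
dilute the estimate — the convention of the common windowed tools; a
called-sites denominator is available by flag. Tajima's $D$ uses the
standard $a_1 \dots e_2$ constants; with missing data the sequence count
$n$ is the rounded mean called-allele count over segregating sites. $S = 0$
returns `NA` (undefined), never 0.

### The called-site-normalized $\pi_n/\pi_s$

The mutational-load estimator works in four steps. (1) Gene models are
screened for quality: the spliced CDS must begin with ATG (strand-aware,
against the model's own haplotype sequence) and its total length must be
divisible by three. (2) Sitewise diversity is summed over sites with HIGH
or MODERATE effect inside those high-quality models. (3) The denominator is
the number of confidently *called* positions inside high-quality models
from an all-sites genotyping run (monomorphic positions included),
multiplied by $2/3$ — the operational assumption that every third coding
position is synonymous. (4) $\pi_s$ sums diversity over intergenic sites
(all gene-model spans excluded, with no buffer around genes — configurable)
divided by the intergenic called-position count. The called-site
normalization is the point: with missing data, the mean diversity would
otherwise be driven by how many positions could be called at all. The
ratio is reported only when $\pi_s > 0$.

## Differentiation, linkage and admixture

$F_{ST}$ is the Weir–Cockerham (1984) variance-component estimator: per
site the among-population ($a$), among-individual ($b$) and within-
individual ($c$) components, combined as the weighted ratio-of-sums
$\theta = \sum a / \sum(a+b+c)$ per 100-kb window and genome-wide. The
ratio-of-sums (not mean-of-ratios) form matches the "weighted" output of
the standard VCF tooling. Sites monomorphic overall, or with no called
diploid in some population, are skipped.

LD is the squared correlation $r^2$ of genotype dosages for all site pairs
within 500 kb after a strict minor-allele-count filter (MAC > 4). Pairs
with $r^2 > 0.01$ are reported and fitted with
$r^2 = \beta_0 + \beta_1 \log_{10} d$; the "initial value" $r_0$ — not
defined by the sources this formalizes — is taken as the fitted value at
the smallest observed distance, and the half-decay distance inverts the
line at $r_0/2$. A non-negative slope leaves the half-decay undefined. LD
pruning works in 50-SNP windows advanced by 10 SNPs: each pair above
$r^2 = 0.1$ loses its lower-MAF member, ties removing the larger
coordinate, which makes the output deterministic.

The $f_3(C; A, B)$ statistic averages $(c-a)(c-b)$ over sites. Because the
sampling noise of $\hat c$ biases the product upward by
$\mathrm{Var}(\hat c)$, the default finite-sample correction subtracts
$\hat c(1-\hat c)/(n_C - 1)$ per site ($n_C$ = called allele count in the
target), the unbiased-heterozygosity form. Standard errors come from a
delete-one block jackknife over contiguous blocks of 5,000 SNPs by default;
$Z = f_3/\mathrm{SE}$, and $Z < -3$ is the usual admixture call. The
per-sample inbreeding coefficient is the method-of-moments
$F = (O_{hom} - E_{hom})/(L - E_{hom})$ with
$E_{hom} = \sum_s [1 - 2pqn/(n-1)]$ — the `--het` convention — which goes
negative for F1 hybrids of diverged parents (excess heterozygosity), the
diagnostic used to spot hybrid accessions.

## Kinship and the cultivation-history graph

Kinship uses the KING-robust within-pair estimator,
$$\phi = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{2\min(N^i_{Aa}, N^j_{Aa})}
  + \frac12 - \frac{N^i_{Aa} + N^j_{Aa}}{4\min(N^i_{Aa}, N^j_{Aa})},$$
chosen over the between-family estimator because it is independent of
sample composition and population structure — essential in a panel that
mixes two diverged wild populations with related cultivars. Degrees follow
the standard $2^{-(d+3/2)}$ cutoffs (duplicate above 0.3536, then 1st/2nd/
3rd degree, unrelated below 0.0442). IBS0/IBS1/IBS2 fractions are reported
alongside $\phi$ as plain site-sharing counts; no HMM segment inference is
attempted. The cultivation-history graph links each sample to its
highest-$\phi$ partner when that $\phi$ is positive, ties broken
lexically; samples with no positive kinship stay isolated.

## Allele-specific expression

The DEA (differentially expressed alleles) test is deliberately the
simplest defensible allele-balance test: per gene and library with at
least 10 reads summed over both alleles, an exact two-sided binomial test
of $\theta = 0.5$, Benjamini–Hochberg correction within the library, and a
call at $q < 0.05$. All three constants are configurable. The saturation
curve draws random $k$-subsets of libraries and reports the mean union of
their DEA sets; when $\binom{n}{k}$ is no larger than the replicate budget
the enumeration is exhaustive and the value exact. Both the per-library
sets and their union are exposed, since a published DEA total may be
either.

Allelic $K_a/K_s$ uses Nei–Gojobori (1986) with Jukes–Cantor correction,
chosen for closed-form auditability: potential sites per codon averaged
over the two sequences (changes to stop codons count as nonsynonymous),
observed differences averaged over mutation paths with
intermediate-stop paths excluded (falling back to all paths if every path
is blocked), and $d = -\tfrac34\log(1 - \tfrac43 p)$. A shared terminal
stop codon is trimmed; internal stops and length mismatches are errors.
The estimate is symmetric in the sequence order.

## The deletion marker

Coverage is averaged in fixed 800-bp windows and normalized by the
sample's genome-wide mean depth. A deletion genotype is called from the
mean normalized ratio over the deletion region with cutoffs 0.25 and 0.75
— the midpoints between the expected copy ratios 1, 0.5 and 0 for zero,
one and two deleted copies. Group comparisons use a pooled-variance
Student's t-test by default (Welch by flag). The in-silico PCR engine does
exact matching only (no mismatches, no degenerate bases) on both strands;
the three-primer design — forward upstream (`a1`), reverse inside the
deletion (`b1`), reverse downstream (`c1`) — distinguishes the three
diploid configurations because the `a1`+`c1` product only fits under the
amplicon-length cap once the deletion shortens the template, while
`a1`+`b1` requires the non-deleted haplotype.

## Demographic trajectory matching

Sequential coalescent methods output piecewise-constant $N_e(t)$
trajectories. The inbreeding correction rescales one population's
generation time (times multiplied by a factor, canonically 3 for a heavily
selfing population; $N_e$ untouched; factors compose multiplicatively).
"Matched" trajectories are formalized as uniform log-$N_e$ agreement into
the past: both trajectories are evaluated on a common grid and the split
time is the most recent grid time $\tau$ with
$|\ln N_e^A(t) - \ln N_e^B(t)| \le$ `tol_log` (default 0.1) for all grid
times $t \ge \tau$. The grid is the union of both trajectories'
breakpoints (optionally augmented with log-spaced fill points) rather than
a purely log-spaced grid: for step functions the breakpoint union is exact
and recovers a planted divergence time exactly, which a fixed log grid
cannot guarantee. The matching itself was a manual step in the analyses
this formalizes, so both the criterion and its default tolerance are this
package's own definition.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth:

* **Genotypes** follow the Balding–Nichols model: per site an ancestral
  frequency $p$ (default uniform on (0.05, 0.95)), each source
  population's frequency Beta-distributed with mean $p$ and variance
  $p(1-p)F$. $F$ is the drift parameter the $F_{ST}$ machinery should
  recover. Within-population inbreeding is a probability $F_w$ of copying
  the first allele, giving an expected heterozygosity deficit of exactly
  $F_w$; F1 samples take one haplotype per source population. The model
  was chosen over forward simulation because $F_{ST}$ is controllable, the
  cost is linear in sites, and expectations are analytic.
* **Pedigrees** drop Mendelian alleles at unlinked sites; clones copy a
  parent verbatim. Truth degrees come from the standard recursive pedigree
  kinship with founders taken as unrelated.
* **Genomes** are built as two haplotypes differing by SNPs and short
  indels at about 2.3 events per 100 bp (the heterozygosity scale of a
  highly heterozygous cultivar), with well-formed single-transcript gene
  models (ATG start, in-frame stop, GT..AG introns, 60-bp UTRs), an
  optional malformed fraction to exercise the quality filter, and a
  planted intergenic deletion (default 3,781 bp) whose 1-kb flanks stay
  indel-free so marker product lengths differ by exactly the deletion
  length.
* **Allelic counts** are Binomial(depth, $\theta$) with $\theta = 0.5$
  for balanced genes and a planted $\theta$ (default 0.8, direction
  randomized) for DEA genes; depth is Poisson (default mean 100, the scale
  at which the binomial test is decisively powered).
* **Coverage** is per-base Poisson with the rate scaled by $(2-g)/2$
  inside the deletion for $g$ deleted copies.

All randomness flows through a single seed; each generator derives its
sub-stream by a fixed offset, so outputs are independently reproducible
and byte-identical across runs.

What the generator does *not* emulate: linkage and recombination (sites
are independent, so LD structure beyond pedigree sharing is absent),
sequencing error, reference bias, indel-rich alignment artifacts, or
read-level data (counts and depths are simulated directly, never FASTQ).
Passing the recovery suites therefore demonstrates estimator correctness
under the stated models, not robustness to alignment pathologies of real
resequencing panels.

## Problem sizes and numerical conventions

The validation suites use sizes at which the expectations are sharp but
runs stay quick: 10,000 independent sites for $F_{ST}$ recovery (observed
error well under the ±0.02 band at $F \in \{0.05, 0.15, 0.30\}$) and for
pedigree-degree recovery (all 120 pairs correct in the shipped
configuration), 20,000 sites for frequency-conservation checks, 1,000
genes × 10 libraries for DEA operating characteristics, and 100 random
toys per oracle-equivalence check at $10^{-9}$ tolerance. Undefined
quantities (zero denominators, $S = 0$, non-negative LD slopes,
unmatchable trajectories) are reported as `NA` with a reason where
useful, never as 0. Genome-scale published values that depend on an
unavailable resequencing panel (panel-wide $\pi$ and Tajima's $D$, LD
half-decay distances, absolute $N_e$ and split-time estimates, the DEA
total) are outside what synthetic recovery can certify; the suites cover
the estimators, not those numbers.

## Known limitations

One transcript per gene, no canonical-transcript logic, and no regulatory
or NMD annotation in the effect classifier (splice effects are folded into
HIGH only when an indel truncates an exon boundary). No segment-based IBD;
kinship is genotype-count based. The binomial DEA test ignores
overdispersion between libraries. In-silico PCR has no mismatch tolerance.
Trajectory fitting itself (SMC-type inference) is out of scope — the
package consumes fitted trajectories as TSV.
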