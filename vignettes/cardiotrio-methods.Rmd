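---
title: "Models and methods behind cardiotrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiotrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotrio)
library(dplyr)
```

cardiotrio implements the statistical machinery of a trio-sequencing
rare-variant study: a null model for de novo mutation (DNM) counts, a
Poisson burden test against that null, a genotype-filter cascade for trio
inheritance classes, carrier-collapsing case/control tests, CNV interval
algebra, and hypergeometric enrichment of candidate genes in single-cell
coexpression modules. This vignette explains each model, the tunable
parameters and their defaults, what the synthetic cohort generator does
and does not emulate, and the design decisions taken where the
methodology left room.

## The mutational model

For every gene we enumerate each coding base and each of its three
possible substitutions, look up the baseline per-generation mutation
probability for the trinucleotide context (the reference base plus its 5'
and 3' neighbours), and sum the probabilities within consequence classes:
synonymous, missense (with a damaging-missense sub-mass), nonsense,
essential splice, start loss and stop loss. Three rules complete the
model:

* **Cross-transcript consequence.** A substitution is classified against
  every transcript and takes the most damaging annotation, under the fixed
  severity order nonsense > essential splice > start loss > stop loss >
  missense > synonymous. The order itself is a design choice (the usual
  annotation-tool convention); only the "most damaging" rule is inherent
  to the method.
* **Frameshift mass.** There is no indel context model; the frameshift
  class probability is defined as 1.25 × the gene's nonsense probability,
  applied after the substitution sums.
* **Coverage masking.** Sites where more than 10% of samples are covered
  by fewer than 8 reads cannot contribute called DNMs, so their
  probability is set to zero (the mask is an input, as a
  `contig`/`pos` table). No other depth adjustment is applied, and no
  divergence-score rescaling exists anywhere in the model.

Essential splice sites are taken as the two intronic bases on each side of
each internal coding-exon junction; transcripts that skip an exon simply
have no splice mass at the skipped junctions. Rate tables are
strand-symmetrized at load (a context and its reverse complement resolve
to the same rate), and CpG contexts carry methylation-level entries with
`"high"` as the default level when no methylation track is supplied —
non-CpG contexts ignore the level. The damaging-missense predictor is an
injectable function; the shipped default is a deterministic, seedless
stand-in that flags ~40% of missense substitutions, adequate for
exercising the damaging aggregates but carrying no biological meaning.

Start-loss and stop-loss probabilities fall out of the same enumeration as
every other class (any substitution in the initiator codon is a start
loss; substitutions in the terminator are stop losses unless the codon
remains a stop). In-frame indels get no expectation mass at all — but see
the burden test below.

## The Poisson burden test

With $N$ trios and per-gene class probability $p_c(g)$, the expected
number of class-$c$ DNMs in a gene set $S$ is

$$E = 2N \sum_{g \in S} p_c(g),$$

the factor 2 converting a per-chromosome rate to a diploid genome. The
observed count $O$ is compared one-sided (enrichment only):
$p = P(X \ge O)$ for $X \sim \text{Poisson}(E)$, and fold $= O/E$.
Aggregates pool class-level $O$ and $E$: loss-of-function (LoF) pools
nonsense, essential splice and frameshift; "damaging" pools LoF and
damaging missense; "protein-altering" pools everything except synonymous.
In-frame and stop-loss-adjacent indel events observed in a cohort are
counted in $O$ for the protein-altering aggregate even though the rate
model gives them no mass — the aggregate is therefore slightly
anti-conservative, which we prefer to silently discarding observed
events. No multiple-testing correction happens inside the burden module;
callers testing many sets apply `bh_fdr()`.

## The filter cascade

Site/genotype QC mirrors a joint-calling pipeline's hard filters:
genotypes with GQ < 20 or DP < 8 are set missing first, then sites are
dropped for quality < 30, mapping quality < 20, parental Hardy–Weinberg
exact p < 1e-5, or missingness > 10%. The HWE test is the conditional
exact test (sum over heterozygote counts no more probable than the
observed one). Records are sparse — a (trio, site) row absent from the
table is an implicit clean homozygous-reference call — so the cohort size
feeds the HWE and missingness denominators.

Classification rules, applied after QC:

* **De novo**: alternate allele present in the child, both parents
  confidently homozygous reference, population allele frequency < 1% in
  every database column, and (for heterozygotes) alternate allele ratio
  ≥ 25%. Whether "absent in parents" means genotype 0/0 or zero
  alternate reads is genuinely ambiguous; we use the genotype plus a
  configurable cap on parental alternate reads, default 1.
* **Homozygous recessive**: both parents heterozygous with allele ratio
  ≥ 25%, child homozygous alternate with ratio ≥ 75%, plus the active
  rarity/damaging rule.
* **Compound heterozygous**: two distinct qualifying child-heterozygous
  variants in one gene, each inherited from a different parent (trans by
  transmission); both members must pass the damaging rule — the
  both-members requirement is an assumption we make explicit rather than
  an established convention.
* **Rarity/damaging modes**: `strict` = MAF < 0.001 and an ensemble
  damaging-missense flag; `relaxed` = MAF < 0.01 and scaled
  deleteriousness score > 20. LoF consequences qualify under either.
* **Ultra-rare damaging** (panel genes): zero frequency in every
  database column *and* no presence flag (an AF of exactly 0 with the
  flag set counts as present), absent from the internal disease-control
  cohort, and LoF or missense with score > 20 (strict inequality).
* **Pseudocontrols**: at a Mendelian-consistent biallelic site the
  untransmitted genotype is `father + mother − child` in alternate-allele
  counts. When all three members are heterozygous the transmission is
  ambiguous, but both phasings give the unordered genotype 0/1, so the
  tie-break is forced rather than arbitrary. Inconsistent sites
  (including true de novos) are skipped and logged.

Allele-ratio criteria use the same AD fields for SNVs and indels.

## Case/control carrier tests and proportions

Carrier collapsing counts each individual once regardless of how many
qualifying variants they carry; the association test is either the
two-sided Fisher exact test on the carrier 2×2 table (default) or a
CMC-style collapsed-indicator chi-square without continuity correction.
Cohort proportions are reported with the Wilson score interval: we
confirmed numerically that Wilson reproduces printed intervals of the
form 14/146 = 9.6% (5.8%–15.5%) where Clopper–Pearson does not
(5.3%–15.6%), and fixed it as the default on that basis.

## CNV region logic

Coordinates are 0-based half-open internally (BED dialect), converted at
the VCF boundary. Two CNVs are *highly overlapping* when the overlap
exceeds 50% of **both** lengths — strictly, so a boundary of exactly one
half fails. De novo CNVs are child calls with no highly-overlapping
same-type parental call in the same trio (breakpoint jitter makes exact
matching inappropriate; the 50% rule is reused) and no highly-overlapping
gold-standard population CNV. The copy-number variable region at a locus
is the shortest reference deletion with >50% reciprocal overlap with
*every* cohort deletion at that locus; cohort deletions are grouped into
loci as connected components under any overlap, since a genome-wide
universal quantifier would be vacuously unsatisfiable — ties break to the
leftmost start. The minimal critical region is the plain interval
intersection of same-type CNVs. Mosaic flagging reflects the mixture
arithmetic of a deletion present in a fraction of cells: depth ratio
inside (0.6, 0.9) — e.g. 0.75 for a ~50% cell fraction — and, when
heterozygous-SNP allelic ratios are available, a mean deviation from 1/2
strictly between 0.05 and 0.45 (shifted, but short of the
loss-of-heterozygosity extreme). These margins are configuration
conventions, not estimates.

## Module enrichment and aggregate scores

Enrichment of a target set in a module is the upper-tail hypergeometric
probability $P(X \ge k)$ (inclusive; the equivalent formulation
$P(X > k-1)$ is the same number) with expected successes $nK/N$ and fold
$k/\text{expected}$. The universe defaults to whatever gene vector the
caller supplies; we recommend the intersection of the expectation-table
and expression-matrix genes, and make no claim about matching any
external calculator's universe. Benjamini–Hochberg q-values are computed
within each target set. Aggregate module scores normalize each cell to
10,000 counts, log1p, z-score each gene across cells, then average over
module genes and stage cells — an emulation of the usual
aggregate-expression convention, not a bug-for-bug reimplementation of
any particular tool.

## The synthetic cohort generator

The generator exists so that every downstream stage has a test oracle: it
returns the exact list of planted events alongside the data.

* **Toy genome.** Non-overlapping genes (about ten per contig), 1–3
  transcripts of 1–10 coding exons, exon lengths multiples of 3 so
  exon-skipping isoforms stay in frame, ATG start, terminal stop, no
  internal stops on any isoform, canonical GT..AG introns.
* **Rates.** Lognormal around 1e-6 per site per generation, transitions
  ×4, methylated CpG transitions ×12 further, capped at 9e-5. The mean is
  deliberately above the human genome-wide average: the toy genome is
  thousands of times smaller than an exome, and this scaling keeps
  per-trio DNM counts in a realistic range (~0.1–1 coding DNMs per trio)
  so that burden tests on a few thousand simulated trios see realistic
  counts.
* **DNM planting.** Per gene and class, counts are drawn
  Poisson($2Np_c(g)\lambda_g$), where $\lambda_g$ is the configured fold
  inside the designated enriched set and 1 elsewhere; sites are drawn
  within a class proportionally to their baseline rate, and frameshift
  events are planted as 1-bp insertions at 1.25 × the nonsense rate. The
  recovery property — the observed/expected ratio in the enriched set
  converges to the planted fold — is checked at 5,000 trios in the
  acceptance suite.
* **Recessive and ultra-rare planting.** Designated genes carry one (or,
  for compound-het genes, two) rare damaging sites; parents are drawn
  from Hardy–Weinberg at allele frequency `recessive_carrier_freq / 2`
  (so planted sites survive the parental HWE filter), children by
  Mendelian transmission. One event of each mechanism is forced into
  fixed trios so small cohorts always contain truth. A 3-gene panel
  carries inherited ultra-rare damaging variants; de novo events that
  happen to land in panel genes and qualify are added to the ultra-rare
  truth, since the caller is right to report them.
* **Background polymorphisms.** Two common sites per gene (allele
  frequency 0.05–0.4) exercise the frequency filters; their records are
  emitted sparsely (only trios carrying the alternate allele).
* **Read support.** DP ~ Poisson(mean depth), alternate depth ~
  Binomial(DP, f) with f = error rate, 0.5 or 1 by genotype, and
  GQ = min(99, 3·DP·(1 − 2|ab − E(ab)|)) — a deterministic monotone
  function of depth and allele balance so the GQ ≥ 20 mask is
  exercisable. At `seq_error_rate = 0` read support collapses to its
  expectation (DP = mean depth exactly, AD rounded), which is what makes
  the "noise-free cohort equals ground truth exactly" property a clean
  equality rather than a statistical statement.
* **CNV call set.** A fixed constructed scenario: a three-deletion locus
  whose reference catalogue contains exactly one qualifying (and
  shortest) copy-number variable region deletion, an isolated de novo
  deletion, an inherited deletion at ~95% reciprocal overlap with a
  parental call, a gold-standard-matched deletion, a mosaic deletion
  (depth 0.75, shifted allelic ratios), and a duplication pair defining a
  minimal critical region.
* **Expression.** Modules share a stage-profile (baseline 2, one peak
  stage at 16, cycling across stages) observed through Poisson sampling
  with lognormal gene noise; `noise = 0` yields the means exactly, so
  module columns are identical in the no-noise limit.

What the generator does **not** emulate: read-level data, linkage
disequilibrium, population structure, a realistic site-frequency
spectrum (the parental frequency distribution is a free parameter, not a
cohort claim), mosaic SNVs, X-chromosome inheritance, or dropout/doublet
artefacts in the expression matrix. Green tests therefore demonstrate
that the algorithms are implemented correctly, not that they are robust
to every artefact of real cohort data.

## Numerical choices

Poisson and hypergeometric tails come from the standard distribution
functions and are verified against term-by-term summation / combinatorial
enumeration to 1e-12 in the test suite. The exact HWE p-value is computed
from the log-factorial closed form with softmax normalization, using a
`(1 + 1e-9)` relative tolerance when collecting outcomes no more probable
than the observed one; the tests cross-check it against the recurrence
formulation. Degenerate inputs follow explicit conventions: $O = 0$ gives
$p = 1$; $E = 0$ leaves fold undefined (NA); an empty universe, empty
target list, zero-size cohort arm, or degenerate interval is an error; a
monomorphic site has HWE p = 1. Problem sizes in the tests (toy genes for
exhaustive enumeration, 60-gene/5,000-trio cohorts for recovery, N ≤ 60
for hypergeometric enumeration) were chosen so that each oracle is exact
or its Monte-Carlo error is quantifiable; the fold-recovery check uses a
±3·SD(O/E) band with O ~ Poisson(fold·E).

## Interfaces

All functions take and return tibbles (or small S3 wrappers over them
with `tidy()`, `glance()`, `autoplot()` methods), so pipelines compose
with the pipe. On-disk interchange uses VCF 4.2 (GT:AD:DP:GQ, one column
per trio member), BED-like TSV for CNVs, and plain TSV for rate tables,
gene models, expectations and classified variants. There is deliberately
no command-line wrapper: the package targets interactive R analysis and
scripted pipelines, and `scripts/acceptance.R` shows the scripted form.

## Known limitations

* The damaging-missense default is a stand-in; real analyses must inject
  a real predictor, and the damaging aggregates inherit its calibration.
* The indel model is the 1.25 × nonsense frameshift rule only; in-frame
  indels have observed counts but no expectation.
* Compound-het phasing relies on parental transmission only; two
  variants both carried by one het parent cannot be phased and are
  (correctly) never paired, but neither can genuinely trans pairs whose
  parents are both carriers of both variants.
* The CNV module assumes biallelic autosomal copy number and does not
  model overlapping mosaic fractions beyond the single depth/allelic
  window.
* Aggregate module scores assume stage labels are given; no trajectory
  or module discovery is performed.
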