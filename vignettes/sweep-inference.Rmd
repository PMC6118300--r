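---
title: "Detecting an incomplete sweep around a deletion-tagging haplogroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting an incomplete sweep around a deletion-tagging haplogroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

Some structural variants — notably whole-gene deletions flanked by
segmental duplications — sit in genomic regions where recurrent
rearrangement and recombination erode linkage disequilibrium. Standard
haplotype-based selection scans cannot be applied to the variant itself;
instead one works with a *haplogroup*: a set of phased haplotypes defined
by shared derived alleles at a core set of mutually linked SNVs, which
tags the structural variant imperfectly. The question this package
answers is whether such a haplogroup, observed at high frequency in one
population and (nearly) absent in another, got there by drift or by an
incomplete selective sweep.

Three lines of evidence are combined, each against an explicit null:

1. **Population differentiation.** The per-site Weir–Cockerham FST of the
   haplogroup's core SNVs is ranked against FST values of simulated
   neutral variants *matched on derived-allele frequency* in the focal
   population. Matching matters: FST is frequency-dependent, so an
   unmatched null would be anti-conservative.
2. **Within-haplogroup diversity.** A sweep multiplies one haplotype, so
   nucleotide diversity *inside* the haplogroup should be far below both
   the surrounding background and frequency-matched neutral carrier
   groups.
3. **Haplotype homozygosity.** Individuals homozygous for the core allele
   should show long runs of homozygosity (ROH) around it relative to
   neutral carriers of frequency-matched simulated variants, because
   recombination has not yet had time to shuffle the swept haplotype.

A non-significant bootstrap check (resampling member haplotypes into
artificial homozygous diploids) guards against sample-composition
artefacts such as consanguinity, and three fast non-selective estimators
date the haplogroup and the putative sweep onset.

## The coalescent engine

The nulls come from the package's own Hudson-style coalescent simulator
with recombination (`simulate_coalescent()`), driven by ms-style command
strings (`parse_ms_args()`), supporting `-t`, `-r`, `-I`, `-m`, `-n`,
`-en` and `-ej`. Conventions: time in units of $4N_0$ generations; a
lineage pair in a deme of relative size $x$ coalesces at rate $2/x$;
lineages migrate backwards at rate $M_{ij} = 4N_0 m_{ij}$; crossovers hit
a lineage at rate $\rho$ times the span of its ancestral material
(trapped material included); infinite-sites mutations fall at rate
$\theta$ per unit branch length, so $E[S] = \theta \sum_{i<n} 1/i$.
`-m i j x` is applied exactly as a single directed entry, and `-ej t i j`
moves every deme-$i$ lineage to deme $j$ and switches off migration into
the vanished deme. Deme indices are 1-based on the command line and
converted once, in the parser.

Design notes:

* Mutations are bookkept per lineage lifetime: when a lineage is
  destroyed, each of its ancestral segments receives a Poisson number of
  mutations proportional to (lifetime × segment length), with carriers
  given by the segment's descendant set. This is exact and avoids
  storing the ancestral recombination graph.
* Segments that reach their marginal MRCA are dropped immediately, so a
  replicate ends when no ancestral material is left.
* The RNG is a self-contained xoshiro256++ seeded through splitmix64
  from (root seed, replicate index): every replicate has its own stream,
  results are independent of R's RNG state, and any replicate can be
  regenerated alone.
* Simulated positions live on $[0,1)$ and are mapped to physical
  coordinates as $\lfloor p L \rfloor + 1$ with collisions bumped to the
  next free base pair (`positions_to_bp()`), because the ROH statistics
  need bp distances.

The engine is validated in the test suite against closed forms
($E[S]$, $E[\pi]$, the $1/i$ frequency spectrum), against a discrete
Wright–Fisher oracle (Kolmogorov–Smirnov on the distribution of $S$), and
— during development — against an independent ms-compatible simulator on
the package's two canonical command lines. One statistical subtlety is
worth recording: sites within a replicate share one genealogy, so pooled
site-frequency-spectrum counts are overdispersed relative to a
multinomial, and a textbook chi-square test on pooled counts rejects a
*correct* simulator. The suite therefore tests each frequency class with
clustering-robust standard errors computed across replicates.

## Frequency-matched nulls

`freq_matched_fst_null()` retains, from every simulated replicate, the
per-site FST of each segregating site whose derived-allele frequency in
the focal deme falls in the matching window (default $[0.69, 0.70]$,
the band used throughout the package's canonical configuration).

`freq_matched_pi_null()` computes nucleotide diversity among the focal
deme's *carriers* of each matched site. Matched sites in complete LD
define the same carrier haplogroup; because the diversity is a property
of the carrier group rather than of the site, the default retains **one
value per distinct carrier group per replicate** (`per_site = TRUE`
restores per-site retention). Under low recombination the two rules give
materially different counts, so both are exposed and the retained count
is always recorded in the result's provenance (`glance()`).

`roh_null()` conditions on "core" sites: frequency inside the window in
the focal deme (default $0.69 \pm 0.031$, a binomial-standard-deviation
band) *and exactly zero* derived copies in the reference deme. Carriers
are paired, within each replicate, into homozygous diploid constructs by
a seeded shuffle, and the run of homozygosity is measured on both sides
of the core. The ROH boundary convention is deliberately simple: the run
ends *at* the first discordant site (length = discordant position −
core position), not at the midpoint of the flanking interval; with no
discordance the run extends to the region edge. The convention is stated
here because it shifts lengths by half an inter-site gap on average and
matters when comparing absolute numbers across tools.

The observed quantity is the mean *downstream* one-sided ROH of
core-homozygous individuals (one-sided because an upstream recombination
hotspot truncates the upstream flank in the motivating use case); it is
doubled before comparison with the two-sided simulated null, which
assumes symmetry of the undisturbed process. Observed and null are
compared with a two-sided Wilcoxon rank-sum test with continuity
correction (`empirical_null_test()`), which also serves the empirical
random-region nulls built with `sample_random_regions()` (uniform
size-matched placement, optionally restricted to overlap an interval
set such as segmental duplications).

## The synthetic panel generator

`generate_sweep_panel()` exists so that every downstream stage is
testable without external genotypes. It emulates, with ground-truth
labels:

* a two-population phased panel (defaults 206 + 216 haplotypes over
  8,787 bp);
* a derived haplogroup at frequency 0.70 in population A, absent in B;
* within-haplogroup diversity several-fold below background
  ($1.2\times10^{-4}$ vs $7.6\times10^{-4}$ per site);
* a deletion allele carried by 91% of members with
  haplogroup–deletion $r^2 = 0.47$;
* optionally, an upstream recombination hotspot.

Backgrounds are drawn from the package's own simulator under a
symmetric two-island model. In that model the expected within-deme
pairwise diversity is $2\theta$ per region independent of the migration
rate, which fixes $\theta = \pi_{bg} L / 2$; the island migration rate
(4N₀m = 5) sets a mild baseline differentiation so that core sites
dominate the FST ranking. Because a single coalescent draw has large
evolutionary variance in realized diversity, the generator uses a high
background crossover rate (0.03 per bp, capped at 1500 per region) and
*conditions* the draw: it is repeated until both populations' realized
diversity lands within `pi_tolerance` (default 15%) of the target. This
is a fixture-generator design choice — the conditioning changes the
background's genealogical variance, which none of the shipped analyses
use.

The haplogroup is star-like around an anciently diverged founder that is
ancestral at every background site and derived at `n_core` (default 6)
fully linked core SNVs. Each member copies the founder and receives
private mutations at new sites; the total private count is fixed at its
expectation $n_{mem}\, \pi_{hg} L / 2$ so that realized member-pair
diversity is stable at $\pi_{hg}$. The founder design reproduces the
empirical situation in which the top-differentiated sites are mutually
linked ($r^2 > 0.84$) and tag a single haplotype group; had the founder
been a random background haplotype, its hitchhiking background alleles
would out-rank the cores with only moderate mutual LD and no coherent
core set would exist.

The deletion is assigned by two conditional carriage probabilities:
$a = P(\mathrm{del}\mid\mathrm{member})$ is given (0.91) and
$b = P(\mathrm{del}\mid\mathrm{non\!-\!member})$ is solved in closed form
from the target $r^2$:
$$ r^2(b) = \frac{q(1-q)(a-b)^2}{p_D(1-p_D)}, \qquad p_D = qa + (1-q)b, $$
which decreases from $r^2_{max} = (1-q)a/(1-qa)$ at $b=0$; an infeasible
target is refused with the attainable bound in the message. Carrier
counts are fixed at their expectations per population (a hypergeometric
rather than binomial assignment) so the realized LD profile is stable
across seeds.

The hotspot, when enabled, recombines each member haplotype (with the
given intensity) onto a random background haplotype upstream of a
breakpoint jittered around the hotspot position — truncating upstream
homozygosity while leaving the downstream flank intact, which is what
motivates one-sided observed ROH.

What the generator does **not** emulate: the sequence content and NAHR
mutation mechanism of segmental duplications, recurrent deletion
formation, background selection, genotyping or phasing error, and
realistic background LD decay (the background crossover rate is chosen
for variance reduction, not realism). Passing tests on synthetic panels
therefore demonstrate that the *machinery* recovers planted structure
under the stated statistical conditions — not that real data meet those
conditions.

For long-range (200 kb) homozygosity panels the within-haplogroup
mismatch density is a separate dial: the pipeline's default uses
$6.25\times10^{-5}$ per bp, i.e. an expected ~16 kb downstream run for a
member pair, the scale of the observable the panel emulates; the
8.8 kb-region diversity target says nothing about homozygosity tracts
two orders of magnitude longer. The long-range panel also defaults to a
1008-haplotype focal cohort (504 diploids), giving ~240 core-homozygous
individuals and ~700 member haplotypes — the sample sizes at which the
bootstrap's 238 homozygous constructs are meaningful.

## Haplogroup identification and deletion imputation

`identify_haplogroup()` ranks sites by per-site FST, keeping only sites
whose derived allele is *more* frequent in the focal population (a sweep
raises its haplogroup's alleles there; without the restriction, sites
driven down in the focal population by the same sweep can top the
symmetric FST ranking). The top `n_core` sites must be in mutual LD
($r^2$ above the threshold, default 0.84) or the function refuses with
the offending pair — the expected outcome on a neutral panel, which the
pipeline treats as "no coherent haplogroup" and falls back to the single
top site so that the verdict can still be computed (and fail on its own
terms). Membership = derived at all core sites; haplotypes carrying at
least half are flagged as recombinant members.

`impute_deletion()` is deliberately simple — leave-one-out
nearest-haplotype (minimum Hamming) vote, ties resolved by majority then
lowest index — because its role is diagnostic: with haplogroup–deletion
$r^2 \approx 0.5$, no tag-SNV imputation can be accurate, and the
function quantifies exactly how inaccurate.

`cluster_haplotypes()` uses complete-linkage hierarchical clustering on
Hamming distances (`stats::hclust`), with no haplogroup or deletion
input; the deterministic tie-handling of `hclust` makes the tree
invariant to input order.

## Dating

Three estimators, all selection-free by construction:

* **Drift time** (`neutral_time_to_frequency()`): the Kimura–Ohta
  expected age of a neutral allele now at frequency $x$ that entered as
  a single copy, $t = -4N_e\,x\ln x/(1-x)$ generations. The formula is
  injectable (`formula_fn`) so variants can be substituted. Its
  validation oracle is a forward Wright–Fisher simulation; note that the
  matching simulated quantity is the mean allele *age over visits* to
  frequency $x$, not the first-passage time to $x$ — first passage
  systematically undershoots age (by 40–70% in the tested range) because
  an allele's age includes excursions above $x$.
* **Divergence age** (`divergence_age()`): per-site distance of the
  haplogroup from a root haplotype scaled by a human–chimpanzee
  calibration, $t = d / D_{hc} \times T_{hc}$, bracketed by a recent
  (5 My) and an old (12 My) split time.
* **ROH onset** (`sweep_onset_from_roh()`): a sweep of age $t$
  generations preserves runs of length $L$ until $rLt \approx 1$, so
  $t = 1/(rL)$; $r = (1.45\pm0.05)\times10^{-8}$ per bp per generation
  by default, with the uncertainty interval propagated. $L$ is the
  per-individual two-flank total; one-sided means must be doubled (the
  CLI's `--side one` does this).

Defaults $N_e = 10^4$ and 25 years/generation are conventional
placeholders and every estimate echoes its full parameter snapshot.

## The pipeline and reproducibility

`run_full_analysis()` sequences panel → haplogroup → LD profile →
diversity contrast → matched FST/π nulls → ROH null and rank test →
bootstrap → dates, and calls the panel a sweep candidate only when all
three criteria hold: core FST above the 99th percentile of its matched
null, member diversity below the 1st percentile of its matched null, and
ROH rank-sum $p < 0.01$ with the observed median above the null median.
Raw p-values are reported and labelled as such; no multiple-testing
correction is applied across the three tests. Every stage derives its
seed from the master seed, so identical configurations give identical
numbers; artifacts (null distributions with their provenance headers,
the tidy report, JSON summary) are written when `out_dir` is set.

Default replicate counts are the canonical configuration (1000 for the
FST/π nulls, 7000 for the ROH null, 500 bootstrap panels of 238
constructs). The test suite exercises the same code paths at reduced
sizes chosen to keep the default run quick — typically 150–1000
replicates for matched nulls, 500–700 for ROH nulls, 100 kb rather than
200 kb long-range panels — and the acceptance checks state the scale
they use explicitly.

## Known limitations

* Growth flags (`-G/-g`), gene conversion, `-es` splits and tree output
  are unsupported; unsupported flags are rejected loudly.
* Only biallelic SNVs plus one symbolic deletion are modelled; unphased
  or missing genotypes are errors by design, not imputed.
* The carrier-group vs per-site retention rules for the diversity null
  can differ several-fold in count under low recombination; both are
  documented and recorded in provenance, but results should state which
  rule was used.
* The ROH rank-sum comparison pools pair lengths that are correlated
  within replicates and within core sites; its p-values are therefore
  somewhat anti-conservative, and borderline calls (p near 0.01) should
  be read with that in mind.
* Coordinates are 1-based fully closed throughout; BED-standard input
  must be declared as such when read.
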