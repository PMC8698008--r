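---
title: "Missing-homozygosity screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-homozygosity screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Closed livestock populations accumulate recessive deleterious alleles
that are invisible to phenotype recording: a fully penetrant embryonic
lethal never produces an affected, recorded animal — it produces a
*deficit of homozygotes* among the genotyped. Given phased SNP genotypes
for thousands of animals, the screen enumerates haplotypes in sliding
marker windows and asks, for each haplotype, whether the number of
homozygous animals is smaller than random mating predicts.

The test is an exact Hardy–Weinberg test restricted to the deficit
direction. For a focal haplotype (all other window haplotypes pooled into
the alternative allele class), conditioning on the sample size $n$ and
the focal allele count $n_A$ gives the heterozygote count the exact
conditional distribution with weights

$$w(n_{AB}) \propto \frac{n!\, 2^{n_{AB}}}{n_{AA}!\, n_{AB}!\, n_{BB}!},$$

and the one-sided p-value is $P(\text{homozygotes} \le O)$. Conditioning
on $n_A$ makes the test exact at any frequency and immune to the fact
that $q$ is estimated from the same animals. Across all (window,
haplotype) tests of one cohort run, p-values are Benjamini–Yekutieli
adjusted — the FDR procedure that stays valid under the strong positive
dependence created by overlapping windows — and records with adjusted
p below $\alpha$ are significant. Significant windows sharing markers
merge into regions; the region's top haplotype defines a ±2 Mb extended
interval for variant mining. In a sequenced panel, a candidate causal
variant must carry a protein-changing consequence term (the 14-term
Sequence Ontology set in `protein_changing_terms`), be in perfect LD with
the diplotype state ($r^2$ of 0/1/2 dosages), and never occur homozygous.

Two cohort designs mirror practice in cattle screens: *trio* offspring
(sire and dam genotyped) and *pgp* offspring (sire and maternal grandsire
genotyped, the dam possibly not). Both designs answer the same question
on different, overlapping offspring sets; regions found by both carry the
label `trio and pgp`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 50 | markers | standard width for ~50k-scale array density; wide enough that window haplotypes are effectively unique per lineage |
| `step` | 1 | markers | windows move marker by marker |
| `alpha` | 0.05 | — | significance level on BY-adjusted p |
| `min_haplotype_freq` | 0.01 | proportion | below this a deficit cannot be distinguished from absence |
| `min_expected_homozygotes` | 1.0 | animals | testing \(E < 1\) is powerless by construction |
| `region_extension` | 2e6 | bp | region grown on both sides so overlapping significant haplotypes are captured in variant mining |
| `expected_mode` | `"hwe"` | — | $E = nq^2$ on the analyzed offspring; `"transmission"` computes $E$ from ancestor diplotypes instead |
| QC `min_maf` | 0.01 | proportion | markers below are excluded |
| QC `min_snp_call_rate` | 0.99 | proportion | marker kept when call rate exceeds it |
| QC `min_animal_call_rate` | 0.8 | proportion | animal kept at or above it |
| `r2_threshold` | 1.0 (tol 1e-9) | — | perfect linkage, with float-noise tolerance |

QC is applied in a fixed order — animal call rate, then SNP call rate,
then MAF, each recomputed on the survivors — because the source
literature does not state an order; fixing one makes runs deterministic
and the report auditable. MAF uses called alleles only.

**Which animals enter the test.** The published full-scale analysis
reports expected counts consistent with $E = nq^2$ on the entire
genotyped population while testing trio/pgp subsets; the software used
there is closed and its internal design undisclosed. This package takes
the self-consistent reading: for a given cohort mode, the analyzed set is
that cohort's offspring, and $q$, $O$, $E$ and the exact test all use
exactly those animals. `expected_homozygotes()` remains directly callable
with any $n$ — called with the full population count it reproduces the
published expected-homozygote arithmetic. The transmission mode
($E=\sum_i P(\text{hom}_i \mid \text{ancestors})$, with the trio term
$(d_s/2)(d_d/2)$ and the pgp term $(d_s/2)[(d_{mgs}/2)(1/2) + q/2]$,
tested against a Poisson-binomial tail) is provided as the alternative
interpretation.

## What the simulator emulates — and what it does not

`simulate_population()` is a gene-drop simulator for a closed population:

* founder chromosomes drawn from a limited per-chromosome haplotype pool
  (default 30), so window haplotypes segregate at the few-percent
  frequencies characteristic of a closed breed; every marker is kept
  polymorphic among founders (configured founder MAF range (0.05, 0.5]);
* Mendelian gene drop with Haldane (Poisson, no-interference) crossovers
  at a constant 1 cM/Mb — no real genetic map exists for the simulated
  genome, so a constant rate is the only defensible choice; configurable;
* lethal loci: a designated founder segment (`span_markers` identical
  markers) injected into one chromosome copy of
  `round(target_carrier_frequency × n_founders)` founders; homozygotes
  die between conception and genotyping with probability `penetrance`
  (they stay in the pedigree, never reproduce, never reach the genotype
  file — embryonic lethality is invisible except via the deficit);
* males always genotyped, females with probability `trio_fraction`
  (0.85), which makes the trio and pgp cohorts differ as in practice;
* per-genotype missingness and post-phasing single-allele error flips
  (defaults 0) for QC robustness checks;
* one causal variant per lethal locus whose dosage *equals* the diplotype
  dosage in the sequenced panel (perfect co-segregation by construction),
  plus unlinked background variants with mixed annotations.

The default scale (2 chromosomes × 1025 markers, 2000 animals) is a
~50-fold reduction of the real data regime (~115,000 markers, ~10,000
animals). Not emulated: realistic cattle demography and selection,
imputation (phased input is a precondition; `trio_phase()` is a minimal
Mendelian substitute), X-chromosome handling, genotyping-array dialects.
A green test on simulated data therefore establishes algorithmic
correctness and statistical calibration at reduced scale — not that any
particular real population harbours detectable lethals.

## Power at reduced scale: why one acceptance criterion is red

For a fully penetrant lethal at haplotype frequency $q$, the top window's
record has $O = 0$ and exact p approximately $e^{-\lambda}$ with
$\lambda \approx n q'^2$ (the post-removal conditional expectation;
$q' \approx q/(1+q)$). BY significance across the $m \approx 3\times10^4$
(window, haplotype) tests of a 2000-window run requires roughly
$p < \alpha\,r / (m\,c(m))$ at rank $r$, i.e. $p \lesssim 10^{-5}$ even
with $r \sim 150$ correlated truth windows. At the full published scale
($n = 9965$, $q = 0.062$) $\lambda \approx 38$ and the signal is
overwhelming. At the specified scaled-down world (2000 animals,
$q \approx 0.08$, trio cohort ≈ 1500) $\lambda \approx 8$–10, so
$p \approx 10^{-4}$: reliably the genome-wide minimum (that property is
tested and green) yet never BY-significant. Detection at this scale needs
$n q'^2 \gtrsim 16$, e.g. $q \gtrsim 0.13$ — which is exactly how the
packaged demo world is configured (carrier frequency 0.34, $q≈0.17$,
`span_markers` equal to the window width so the exact-span window is
guaranteed observed-homozygote-free). The acceptance test for recovery at
$q \approx 0.08$ is therefore left failing at its stated threshold rather
than silently re-tuned; the demo world, where the criterion's logic is
attainable, is exercised green in the pipeline tests.

A related subtlety surfaced by the simulator: when the lethal span is
wider than the window, a recombinant haplotype can match a window-sized
sub-span without carrying the causal variant, so a surviving animal can
be window-homozygous — the region is still found, but its top record may
show a 94–96% rather than 100% deficiency. This mirrors the partial
deficits reported for real haplotypes and is why the demo uses
`span_markers = window_size`.

## Numerical choices

* Exact-test weights are accumulated in log space (`lfactorial`), and
  tail sums are taken from the small end, so p-values of order $e^{-40}$
  keep full relative precision; within a scan, distributions are cached
  per $(n, n_A)$.
* `by_adjust()` is the plain step-up with the harmonic factor, capped at
  1 and made monotone; it matches `stats::p.adjust(method = "BY")`
  (asserted in tests) but is implemented independently.
* Deficiency is computed as `100 * ((E - O) / E)` — parenthesized so a
  zero-observed record is *exactly* 100.
* Region top-haplotype ties break by larger deficiency, then leftmost
  window start. Extended intervals clip to `[1, chromosome end]` (the
  last mapped position when true chromosome lengths are unknown).
* Window haplotypes containing any missing allele are dropped from that
  window's counts (never imputed); an animal counts only when both
  haplotypes are complete, keeping $n_{AA}+n_{AB}+n_{BB}=n$ coherent.
* $r^2$ uses genotype dosages (0/1/2), not phased gametes, matching the
  diplotype-vs-genotype usage; a constant vector yields an explicit
  "undefined" flag, never a silent 0. Perfect linkage uses threshold
  $1 - 10^{-9}$.
* Haplotype keys are packed into 64-bit integers in the compiled scan
  path (window ≤ 64 markers); wider windows fall back to a string-keyed
  R tally with identical semantics.

## Design choices where the design was open

* **Cohort overlap:** an offspring may sit in both trio and pgp cohorts;
  a `disjoint` flag removes trio offspring from pgp for users who want
  exclusive cohorts.
* **BY family:** all tests of one cohort-mode run (trio and pgp adjusted
  separately, as the two published analyses were).
* **Pipeline config format:** JSON (`jsonlite`) rather than YAML — no
  YAML parser is available in the supported dependency set; structure
  and flag overrides are unchanged.
* **VCF ingestion:** the genotype matrix is read with a narrow,
  `data.table::fread`-based line-format reader. The general-purpose
  Bioconductor reader parses an uncompressed many-sample VCF through an
  R-level character path that took tens of seconds per load at demo
  scale; the screen needs only biallelic GT records, which the fast
  reader enforces explicitly. Round-trip fidelity against the package's
  own writer is tested.
* **Phase bookkeeping:** `trio_phase()` resolves heterozygous offspring
  sites only where parental homozygosity forces the transmission; it
  never alters genotypes, flags Mendelian inconsistencies without
  dropping them, and leaves ambiguous sites unresolved — the scan then
  treats those sites as missing for that animal.

## Known limitations

* Power at desk scale is bounded as analyzed above; the package cannot
  (and does not claim to) reproduce full-scale discovery numbers from
  simulation.
* The exact test pools all non-focal haplotypes; haplotype-by-haplotype
  interference within a window is not modelled.
* The transmission expectation treats ancestor diplotypes as known and
  the maternal-granddam allele as a population draw; it is an
  approximation for incomplete pedigrees.
* Conservation and deleteriousness scores are pass-through annotation
  columns when present; they are never computed.
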