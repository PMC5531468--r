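---
title: "Rare-variant triage for cardiomyopathy gene panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant triage for cardiomyopathy gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioTriage)
```

## The problem

Targeted panels for the inherited cardiomyopathies return on the order of
a hundred candidate variants per proband. The scientific object of
interest is much smaller: the set of *rare* variants compatible with a
dominant disease model, and within it the subset a transparent rule system
is willing to call *potentially pathogenic* — a research label for
gene–phenotype discovery, deliberately distinct from a clinical
(ACMG-style) classification, which this package does not attempt.

`cardioTriage` decomposes the procedure into a rarity filter, a
pathogenicity rule engine, and cohort-level analytics, each testable in
isolation and together against simulated cohorts with recorded ground
truth.

## The rarity filter

A variant observation is retained when three criteria hold
simultaneously: a protein-altering consequence class (missense, nonsense,
stop-loss, canonical splice site, frameshift or in-frame indel), read
support of at least `minDepth` reads, and an aggregated minor allele
frequency no greater than the threshold of the carrier's phenotype.

The tunable parameters live in a `MAFPolicy`:

| parameter | default | units | rationale |
|---|---|---|---|
| threshold, DCM | 0.004 | allele fraction | scaled to phenotype prevalence |
| threshold, HCM | 0.002 | allele fraction | ″ |
| threshold, ARVC | 0.0005 | allele fraction | ″ (rarest phenotype) |
| `minDepth` | 10 | reads | minimal credible support for a call |
| `aggregation` | `max_across_sources` | — | see below |

Prevalence-scaled thresholds are configuration, not computation: no closed
formula maps prevalence to a cutoff, so the three defaults are stated
values and a `policy.yaml` can override them (percent strings with decimal
commas, e.g. `"0,4%"`, are normalised on load).

Frequencies from several databases are aggregated by the **maximum**: a
variant counts as rare only if it is rare in *every* database that has
seen it. This is the conservative reading of "rare in variant databases";
the alternative formulation offered by the enum, `any_source_exceeds`,
rejects as soon as one database exceeds the threshold and is arithmetically
the same test. Absence from every database counts as frequency zero —
never-observed variants are maximally rare, and a fraction of genuinely
novel variants is expected in any cohort.

## The rule engine

Each rare variant receives exactly one branch, in this precedence order:

1. **ClinVar demotion.** VUS / likely benign / benign demotes the variant
   unless HGMD-same-phenotype or published support independently asserts
   pathogenicity. ClinVar-pathogenic cannot rescue here because it is
   mutually exclusive with the demoting classes. The demotion-versus-
   override precedence is genuinely open in principle; this ordering is
   the one that reproduces the curated worked example (including the
   exclusion of a consensus-positive missense variant recorded as VUS)
   while letting an independent HGMD/literature assertion stand. Whenever
   this precedence decides an outcome the call is flagged
   (`precedence_decisive`) so the choice is visible in the rule trace.
2. **TTN missense exemption.** Titin missense variants are common in
   unaffected carriers and show no case–control frequency difference, so
   they are never labelled potentially pathogenic regardless of predictor
   output — and, by construction of the branch order, regardless of
   database evidence.
3. **TTN truncating rule.** See the next section.
4. **Missense consensus.** All four predictors simultaneously damaging
   (SIFT, PROVEAN, PolyPhen-2, MutationTaster). A missing verdict breaks
   the consensus: an unscored variant cannot be called on predictions it
   does not have.
5. **Radical rule.** Nonsense, stop-loss, canonical splice, frameshift
   and in-frame indels are positive on MutationTaster *disease causing*
   alone. Stop-loss follows this rule although none occurs in the curated
   set. An absent MutationTaster verdict gives a negative, overridable
   outcome.
6. **Database override.** A negative outcome of 4–5 flips to positive on
   ClinVar pathogenic (same phenotype), HGMD (same phenotype) or published
   support.

Conservation annotations (Grantham > 100, PhastCons = 1, PhyloP > 1) are
reported as evidence codes but are never decisive: the curated examples
include positive calls lacking them, so they are metadata for the reader,
not rule inputs. Evidence codes are computed identically for positive and
negative calls.

## The titin band map

Truncating TTN variants are positive only when the affected residue maps
to the sarcomeric **A-band** of its transcript *and* lies in the protein
region shared by all isoforms under consideration. Band boundary
coordinates are not part of the rule: they ship as a versioned YAML file
(`inst/extdata/ttn_region_map.yaml`) derived from public titin annotation
— N2B (`NM_003319`, 26 926 aa) partitioned into Z/I/A/M intervals and the
short novex-3 isoform (`NM_133379`, 5 604 aa), which terminates inside the
I-band and therefore contributes no shared region. The default
`isoform_set` is `NM_003319`: "affects all TTN transcripts" is
operationalised as membership in the A/M constitutive region shared by the
full-length isoforms, which novex-3-referred positions can never satisfy.
What exactly "all isoforms" means is ambiguous in the field; the set is
configurable and both sub-tests (band, shared region) are spelled out in
each call's rationale string. The rule logic is validated independently of
the shipped numbers against a toy 100-residue map and a linear-scan
oracle.

## Cohort analytics

Burden summaries include zero-carrier patients in every denominator (a
cohort mean computed only over carriers would overstate the burden);
reported means are rounded to one decimal. The phenotype-overlap partition
assigns each gene with at least one rare variant to exactly one of the
seven non-empty subsets of {DCM, HCM, ARVC}; disjointness and coverage are
enforced by property tests against a brute-force subset computation.

Novelty is operationalised strictly: the pair (gene, carrier phenotype) is
novel iff the `AssociationCatalog` lacks that tag for that gene. A gene
tagged only as a channelopathy gene is therefore novel in *any*
cardiomyopathy — that is the intended behaviour, since observing a
channelopathy gene in a cardiomyopathy cohort is exactly the kind of
association the analysis is after. Genes absent from the catalog
altogether trigger a warning and count as novel by default
(`offPanelNovel = TRUE`). The bundled 115-gene catalog is a best-effort
curation; novelty counts on real cohorts depend on the catalog used and
should be read relative to it.

## The simulator

`simulateCohort()` emulates the reference study design: 16 DCM / 14 HCM /
8 ARVC patients, Poisson candidate counts with means 85/89/92 per
phenotype, Poisson rare counts with means 4.5/3.6/2.4, and a rule-branch
distribution over rare variants (defaults ≈ 10 % missense consensus, 8 %
radical, 1.5 % override, 0.7 % TTN A-band truncating, 2 % demoted, 28 %
TTN-missense-exempt, the rest benign) chosen to mirror the observed
composition of such cohorts, where titin dominates the rare-variant
tallies. Gene assignment uses rank-decaying weights with the heaviest
weights on the genes that dominate real panels, so tally tests exercise a
realistically skewed distribution.

Annotations are *constructed to satisfy exactly one branch*: a planted
radical variant gets MutationTaster disease-causing and no demoting
ClinVar class; a planted-rare frequency sits below the phenotype threshold
with a 20 % margin (or is absent from all databases, probability 0.23);
each planted-common variant fails exactly one inclusion criterion. Truth
is recorded at generation time and never recomputed, which is what makes
"100 % recovery on a noiseless cohort" a meaningful end-to-end test rather
than a tautology. An optional predictor-noise rate corrupts verdicts after
the truth is recorded; consensus recovery then degrades monotonically in
the noise, which is tested.

What the simulator does *not* emulate: linkage between variants, realistic
allele-frequency spectra, per-gene mutation-rate differences beyond the
skew weights, sequencing artefacts, or annotation disagreement between
transcript choices. Passing tests on simulated cohorts therefore
demonstrate the correctness of the *rules and plumbing*, not calibration
of the procedure on real data.

## The curated worked example

`referenceFixtures()` rebuilds, in code, a cohort of 38 probands whose 28
expert-classified potentially pathogenic variants are encoded from their
published annotation codes: a code present means the underlying annotation
is in its flagged state (e.g. `SI` ⇒ SIFT damaging), a code absent the
converse. Per-variant read depths are not published and are set to a
constant 50, above the threshold and never decisive. Individual patient
sexes are likewise not published; the roster carries synthetic sexes
consistent with the cohort-level counts, with the one X-linked *DMD*
carrier male so the hemizygous call is exercised. One splice variant is
carried by two patients, so the cohort holds 29 observations of 28
distinct variants. The package reproduces all 28 calls, their evidence
strings row for row, the 15/5/4/2/2 type tally, the 3 double-carrier and
12 zero-carrier patients, and the single positive TTN truncation.

## Numerical and degenerate-input choices

* Frequencies are fractions on the 0–1 scale everywhere; decimal-comma
  and percent notations are normalised at I/O boundaries only.
* `PhastCons = 1` is tested as exact equality on the stored double (the
  score is reported saturated, not computed); `PhyloP > 1` and
  `Grantham > 100` are strict.
* Unparseable protein tokens classify as `unknown` (a value, not an
  error), and synonymous substitutions map to consequence `other`, which
  the filter excludes.
* Empty cohorts flow through every stage as empty-but-valid objects with
  a warning at the filter.
* A TTN truncating variant with no region map, or a residue beyond the
  transcript length, is an error: the rule cannot be evaluated, and
  silence would mislabel.
* Output files are byte-stable for fixed inputs (fixed column order,
  `"."` for missing, no timestamps), so re-runs are diffable.

## Problem sizes in the test-suite and acceptance runs

Property suites run on study-sized simulations (38 patients, ≈ 3 300
candidate variants) and on exhaustive truth-table grids over the boolean
annotation atoms per consequence class (≈ 10⁴ engine calls); the
large-sample check of the per-phenotype burden means uses 450 simulated
patients. These sizes estimate every tested quantity tightly while keeping
a full run in the low minutes on one core.

## Known limitations

* The engine consumes annotations; it performs no re-annotation, HGVS
  validation against reference sequences, or liftover. Multi-transcript
  annotations are preserved on input but the engine evaluates the
  designated primary transcript of each row.
* The TTN band boundaries are a versioned data artefact, not a claim; a
  study using different isoform annotations should ship its own YAML.
* Novelty detection is only as good as the catalog; the bundled one is a
  reasonable default, not an authority.
* No statistical test of burden differences between phenotypes is
  provided, and none is implied by the summaries.
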