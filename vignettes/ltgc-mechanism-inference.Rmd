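---
title: "Inferring repair mechanisms behind long-tract gene conversion at FS2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring repair mechanisms behind long-tract gene conversion at FS2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fs2ltgc)
```

## The scientific problem

Replication-fork collapse at fragile sites produces double-strand breaks
whose repair by homologous recombination can leave long interior tracts of
loss of heterozygosity (LOH) — long-tract gene conversions (LTGC), defined
as interior LOH of at least 15 kb with heterozygous flanks.  Several
break-induced replication (BIR) outcomes can produce an LTGC, and they
leave distinct physical fingerprints:

* **BIR with a late template switch.**  The invading 3' end copies the
  homolog for more than ~15 kb, disengages, and re-anneals to its own
  homolog.  Only the broken chromosome changes; the SNPs flanking the
  tract are in *coupling* (each homolog carries the same parental alleles
  on both flanks).
* **BIR with half crossover.**  Endonuclease cleavage of the migrating
  D-loop fuses the invading chromosome to the distal part of the template
  and transfers the break to the template, which is repaired by a second
  BIR.  Flanking SNPs end up in *repulsion*, and the template homolog
  gains whatever terminal content it lacked — in the S288c × YJM789
  diploid modeled here, a net ~6 kb of S-specific right-arm terminus.
* **Gap repair.**  The two ends of the break are separated in time and
  engage templates independently.  Re-capture or annealing of the two
  nascent strands leaves a coupling-phased tract indistinguishable from a
  late template switch; cleavage of the distal D-loop instead yields an
  *abrupt allele transition* (adjacent homozygous runs of opposite origin
  at constant coverage); and invasion of a repetitive element on a
  nonhomologous chromosome, resolved by a centromere-retaining half
  crossover, leaves the two arms of the broken homolog on *different
  molecules* ("disjoined").

The package implements the full inference chain used to distinguish these
outcomes: a forward simulator of each mechanism on a block-structured
diploid genome, a generator of per-SNP sequencing observables, callers for
zygosity tracts / CNVs / abrupt transitions, in-silico counterparts of the
physical assays (CHEF karyotyping, Southern probing, PCR-RFLP, junction
Sanger analysis), and the rule-based classifier that assigns each strain
to the Coupling, Repulsion or Disjoined evidence group.

## The genome model

The experimental diploid is two ~0.5%-divergent haplotypes, "S"
(S288c-related) and "Y" (YJM789-related).  Chromosomes are ordered lists
of haplotype-origin blocks; every rearranged product (translocations,
duplications, deletions, captured repeat content) is expressible in the
same representation, and a CHEF gel band is simply the summed block length
of a molecule.

Coordinates are 1-based inclusive with closed intervals.  The two
haplotypes are colinear except where the configuration declares
haplotype-specific segments.  On chromosome III the packaged baseline
encodes, in the S frame: a 5 kb S-only Ty cluster on the left arm, the
hemizygous fragile site FS2 (a 12 kb inverted Ty1 pair on S, faced by a
single 6 kb Ty1 on Y), a 9 kb S-only Ty cluster on the right arm, and a
6 kb S-specific terminal segment.  These sum to homologs of 346 kb (S) and
320 kb (Y).  The terminal segment is deliberately the *net transferable*
6 kb: the strain background is described both as lacking ~9 kb at the Y
right-arm end and as producing half-crossover products only ~6 kb larger,
a discrepancy attributed to unequal Ty content; the model encodes the net
quantity that the half-crossover product actually gains, which is the
quantity every downstream assay sees.

SNP markers live only in shared (colinear) sequence, never inside Ty
elements or repeat regions — repeat-internal markers would be unmappable
in real short-read data.  Haplotype divergence itself is metadata;
nucleotide sequence is materialized only for junction fixtures.  The
default panel density is 1 SNP per 1000 bp with ±250 bp jitter; the
fixture cohort uses 300 bp spacing (closer to the real ~0.5% divergence)
so that the shortest catalogued CNVs (~2 kb) retain five or more markers.
The panel is part of the study design: it is generated from a fixed
configuration seed, so cohorts are identical across runs and only read
sampling responds to the user's seed.

## Observables

Per-SNP observables mimic a mapped-and-counted sequencing table: coverage
is Poisson with mean `depth × copies_total / 2` and the Y-allele count is
binomial with a symmetric miscall rate, giving the characteristic 50% /
100% / 0% allele-fraction tracks and 1×/2×/3× coverage states.  Noise-free
mode stores the expectations exactly and is the reference condition for
the cohort-level checks.  The generator does not model mapping bias, GC
bias, or read-level artifacts; passing tests therefore demonstrate the
logic of the inference, not robustness to alignment pathology.

## Calling

Zygosity calls threshold the Y fraction: ≥ 0.95 homozygous-Y, ≤ 0.05
homozygous-S, 0.35–0.65 heterozygous, coverage < 10 reads excluded.  The
published rules are qualitative ("~50%", "100%"); these cutoffs separate
the states by many binomial standard deviations at the default 100×
depth.  Ambiguous and low-coverage SNPs are skipped without breaking
runs — robustness to the low-coverage strain noted in the source data —
and runs shorter than 3 SNPs are absorbed as noise.  Tract edges are
reported as junction intervals between the last flanking-state SNP and
the first in-state SNP; with 1 SNP/kb these are < 4 kb wide wherever the
junction falls in marker-dense shared sequence, and necessarily widen to
the size of any marker-free hemizygous block they abut (exactly as real
junctions at Ty elements cannot be narrowed).

CNV calling normalizes coverage by the genome-wide median, applies a
5-SNP running median, and thresholds at 0.75/1.25.  Reported bounds are
the in-state SNP extent; the 2 kb minimum-length gate is applied to the
flanking-SNP (outer) extent so that jitter in marker placement cannot
drop a genuine 2 kb event below the gate.  Abrupt transitions are
adjacent homozygous runs of opposite origin with no intervening
heterozygous run and no overlapping CNV call.  In the genome-wide scan,
homozygous runs reaching a chromosome end are terminal LOH (canonical BIR
or reciprocal crossover — indistinguishable here as in the source
system), runs joined by an abrupt transition merge into one flagged
event, interior runs are gene conversions (short < 15 kb / long ≥ 15 kb),
and hemizygous runs fully covered by a 1× call are reported as the CNV
only.  Events whose interior boundary falls in a configured repeat region
(the chromosome XII rDNA array) are flagged.  No multiple-testing control
is applied: the calls are deterministic rules, not hypothesis tests.

## Assays and the classifier

Isolability of a CHEF band uses a 10 kb resolution: a band is excisable
iff no other band lies within 10 kb.  Because observed gel behaviour is
not a clean function of the size gap, each fixture strain also carries an
explicit separability flag reproducing the reported gel outcomes; the
rule-based predicate is exposed (and tested) separately.  Phasing of the
tract flanks types each isolated chromosome III molecule at the
centromere-proximal diagnostic SNP (the MnlI assay at base 113,543:
462 bp amplicon, cut to 335 + 127 bp on the Y allele) and at the nearest
informative SNP on each flank; distal-flank PCR failure is the atypical
signature of a disjoined chromosome.

When the two chromosome III bands cannot be excised, the band-to-homolog
assignment falls back on sizing: a band matching the baseline Y homolog
within the ±2 kb CHEF tolerance is taken as Y; otherwise the assignment
closest to the +6 kb half-crossover signature is adopted.  This mirrors
how the undetermined-phasing strains were placed in the original
analysis, and it is the one place the evidence integration uses the size
signature rather than direct molecular typing.

Group assignment fires rules in a fixed order — Disjoined (arm probes on
different molecules, heterozygous flanks, no chromosome III dosage loss)
before Repulsion (repulsion phasing, or undetermined phasing with the
+6 kb Y signature) before Coupling (coupling phasing, or undetermined
phasing with an unchanged Y homolog) — because arm-linkage evidence is
categorical while phasing can be unavailable.  Consistency of the
repaired-S size with the tract-plus-CNV expectation is advisory: the
quantitative reconstruction is not specified in the source and strain-
specific repeat capture makes it approximate, so its failure is recorded
in the rationale and demotes a strain only when no rule fires.  The
classifier deliberately does not attempt to split the Coupling group into
late template switch versus gap repair; the evidence cannot.

## The fixture cohort

The packaged 16-strain cohort encodes each strain's mechanism and
breakpoints so the simulated CHEF deltas, phasing calls, Southern
patterns and genome-wide catalog reproduce the published per-strain
table.  Two modeling points deserve emphasis:

* **Junction repeat capture.**  Invasion points are confined to ~30 kb
  around FS2, so block arithmetic alone cannot span the observed range of
  repaired-S size changes.  Each strain therefore carries a signed
  repeat-capture term: SNP-free repetitive sequence captured (or copied
  Ty content lost) at the repair junction.  This is not a free fudge —
  the Disjoined strains are *observed* to be up to ~464 kb larger at flat
  2× sequencing coverage, which strictly requires sequencing-invisible
  (repetitive) content, and the source analysis itself allows that size
  gains "could be due to the inclusion of other DNA fragments".
* **Disjoined products.**  The left product is the S left arm plus the
  Y-copied tract plus captured repeat filler; the right product is the S
  right arm attached, via a centromere-retaining half crossover, to a
  nonhomologous chromosome at a subtelomeric repeat tip (the displaced
  tip is marker-free, so no CNV appears — matching the clean catalogs of
  those strains).  Attachment chromosomes and fillers are chosen per
  strain to meet the reported CHA1/PAT1 band sizes.
* **Composite strains.**  The strain with two tracts is modeled as two
  successive template switches in one event; the strain with a deletion
  inside its tract carries a 3-base microhomology junction with a nearby
  2-base island, reproduced by the junction-fixture generator and the
  overlap-scan finder.

Unselected genome-wide events (15 terminal LOH, 5 of them with abrupt
transitions, 8 CNVs, 4 interior conversions) are planted at the
catalogued approximate coordinates; copied origins at unreported detail
level were fixed once to plausible values.

## Randomness, tie-breaks and degenerate inputs

Every stochastic routine takes an explicit seed and restores the caller's
RNG state.  Resection distances are truncated-exponential (mean 5 kb,
max 30 kb) — the source states only that tract ends moved in both
directions from FS2, so a scale matching the observed end displacements
was fixed once.  The random-event sampler used by the round-trip checks
conditions on the screen's own selection criterion (an LTGC-scale tract,
≥ 15 kb): events too small to be selected as LTGC colonies are not part
of the study conditions.  Degenerate inputs behave conservatively: a
template switch back at the invasion point is identity repair; cleavage
at the invasion point gives a zero-length tract; zero-length CNV
intervals are no-ops; deletions crossing a centromere are refused
(acentric/dicentric chromosomes are not modeled); an all-low-coverage
table segments to an empty result with a warning.

## Problem sizes and what the tests show

The cohort runs noise-free at 100× depth over a ~12.1 Mb genome with
~40,000 markers; the full simulate → call → assay → classify pipeline
completes in a few seconds.  The round-trip property (200 seeded
replicates per mechanism at depth 100, error 0; and a smaller replicate
set at 1% miscalls) exercises the whole chain end to end.  Junction
containment is checked over hundreds of simulated events in both
noise-free and sampled modes.  These checks validate the inference logic
under the generative model stated above; they do not certify behaviour on
real alignments, repeat-mediated mapping artifacts, or aneuploid
backgrounds beyond the modeled 1×/2×/3× states.  The median tract length
of the real strains is likewise not reproducible here, because the true
per-strain junction coordinates are not published; breakpoints in the
cohort were chosen to reproduce the *assayable* quantities (sizes,
phasing, catalogs) instead.
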