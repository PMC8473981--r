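# fs2ltgc

Mechanism inference for long-tract gene conversion (LTGC) at the yeast
fragile site FS2.

## What problem this solves, and for whom

Collapsed replication forks at fragile sites are repaired by homologous
recombination, and one puzzling outcome is the *long-tract gene
conversion*: an interior region of loss of heterozygosity (LOH) ≥ 15 kb
with heterozygous flanks.  Several noncanonical break-induced replication
(BIR) outcomes can produce an LTGC, and they predict different physical
fingerprints in a divergent diploid (S288c × YJM789, haplotypes "S" and
"Y"):

| Mechanism | Flank phasing | Homolog sizes | Coverage |
|---|---|---|---|
| BIR + late template switch | coupling | only the broken (S) homolog changes | 2× throughout |
| BIR + half crossover | repulsion | Y homolog gains the S-specific terminus (+6 kb) | 2× throughout |
| Gap repair (recapture / anneal) | coupling | only S changes | 2× throughout |
| Gap repair + half crossover | — | — | abrupt homozygous S↔Y transition, constant 2× |
| Gap repair, ectopic dual BIR | distal-flank PCR fails | repaired S much larger | 2×, arms of S on different molecules |

`fs2ltgc` is for researchers who analyze mitotic LOH/BIR outcomes from
marker panels and whole-genome sequencing: it provides a forward
simulator of each mechanism on a block-structured diploid genome, a
per-SNP observable generator (allele-fraction and coverage tracks), rule
based callers (zygosity tracts with junction intervals, 1×/2×/3× CNV
segmentation, abrupt-transition detection, a genome-wide event catalog),
in-silico versions of the physical assays (CHEF karyotype sizing,
CHA1/PAT1 Southern probing, PCR-RFLP genotyping, junction microhomology
analysis), and the classifier that integrates the evidence into the
**Coupling / Repulsion / Disjoined** grouping with each group's
compatible mechanisms.

At its core the classifier is a fixed-order rule system over the evidence
bundle *(ΔY, ΔS, phasing, arm-linkage, CNVs, tract)*:

1. arms of the S homolog on different molecules + heterozygous flanks at
   2× → **Disjoined** (gap repair with half crossover);
2. repulsion phasing, or undetermined phasing with |ΔY − 6 kb| ≤ 2 kb →
   **Repulsion** (half crossover);
3. coupling phasing, or undetermined phasing with |ΔY| ≤ 2 kb →
   **Coupling** (late template switch or gap repair — indistinguishable).

## Worked example

Simulate a half crossover on the packaged baseline diploid and run the
inference:

```r
library(fs2ltgc)

g   <- baseline_genome()                       # 346 kb "S" / 320 kb "Y" chr III
brk <- make_break(g, list(zero_resection = TRUE))
brk
#> <break at chrIII:174000; tract ends 168000 / 180001 (resection 0+0 bp)>

hc <- simulate_half_crossover(g, brk, 245000)
hc
#> <repair outcome: half_crossover at chrIII:168000-245000, expected group Repulsion>

res <- classify_outcome(hc, g, noise_free = TRUE)
res$evidence
#> <evidence: dY +6000 bp, dS -21000 bp, phasing not_determined, arms same_molecule, 0 chrIII CNV(s), tract 180673-244721>
res$classification
#> <Repulsion group; mechanisms: half_crossover>
#>   - phasing not determined but Y homolog ~6 kb larger
```

Reading the output: the conversion tract (SNPs 180,673–244,721, 100%
Y-allele reads) is interior with heterozygous flanks; the Y-centromere
molecule grew by exactly the 6 kb S-specific terminus it acquired in the
half crossover; the two products (325/326 kb) are too close to excise
from a gel, so phasing is undetermined and the +6 kb signature makes the
call.  The diagnostic PCR-RFLP at chromosome III base 113,543 shows the
heterozygote's three bands:

```r
pcr_rflp(g, assay_snp(g, 113543))
#> [1] 462 335 127     # uncut S amplicon; Y allele cut by MnlI to 335 + 127
```

The packaged 16-strain fixture cohort reproduces the published strain
table end to end:

```r
res <- classify_cohort(generate_fixture_cohort(seed = 1, noise_free = TRUE))
res$report$groups
#>     Coupling    Repulsion    Disjoined Unclassified
#>            7            6            3            0
res$report$unselected
#>      terminal_LOH               CNV   gene_conversion abrupt_transition
#>                15                 8                 4                 5
```

A file-based pipeline (`run_simulate()` / `run_call()` /
`run_classify()`, with an `Rscript` front end in
`inst/scripts/ltgc-pipeline.R`) writes the same results as TSV/BED with a
parameter manifest per stage.

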