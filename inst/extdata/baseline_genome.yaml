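# Baseline configuration of the FS2 experimental diploid (S288c x YJM789
# derived).  Coordinates are synthetic but dimensioned to the real strain:
# chromosome III homologs of 346 kb (S) / 320 kb (Y); the 26 kb difference is
# carried by S-only Ty content, the hemizygous FS2 inverted-Ty1 pair (the Y
# homolog carries a single Ty1 at that spot), and a 6 kb net-transferable
# S-specific terminal segment on the right arm.  All other chromosomes are
# colinear between haplotypes.
genome:
  name: "FS2 experimental diploid (synthetic coordinates)"
  divergence: 0.005
  snp_spacing: 1000
  snp_jitter: 250
  panel_seed: 713
chromosomes:
  - {name: chrI,    size: 230000,  centromere: 151000}
  - {name: chrII,   size: 813000,  centromere: 238000}
  - name: chrIII
    centromere: 114300
    segments:
      - {type: shared, length: 50000}
      - {type: s_only, length: 5000,   name: Ty_left_cluster, kind: Ty_element}
      - {type: shared, length: 113000}
      - {type: s_only, length: 12000,  name: FS2,             kind: fragile_site}
      - {type: y_only, length: 6000,   name: Ty1_Y_at_FS2,    kind: Ty_element}
      - {type: shared, length: 50000}
      - {type: s_only, length: 9000,   name: Ty_right_cluster, kind: Ty_element}
      - {type: shared, length: 101000}
      - {type: s_only, length: 6000,   name: PAU3_terminal,   kind: repeat_region}
  - {name: chrIV,   size: 1532000, centromere: 450000}
  - {name: chrV,    size: 577000,  centromere: 152000}
  - {name: chrVI,   size: 270000,  centromere: 149000}
  - {name: chrVII,  size: 1091000, centromere: 497000}
  - {name: chrVIII, size: 562000,  centromere: 106000}
  - {name: chrIX,   size: 440000,  centromere: 356000}
  - {name: chrX,    size: 745000,  centromere: 436000}
  - {name: chrXI,   size: 667000,  centromere: 440000}
  - {name: chrXII,  size: 1078000, centromere: 151000}
  - {name: chrXIII, size: 924000,  centromere: 268000}
  - {name: chrXIV,  size: 784000,  centromere: 629000}
  - {name: chrXV,   size: 1091000, centromere: 327000}
  - {name: chrXVI,  size: 948000,  centromere: 556000}
features:
  - {name: CHA1,   chrom: chrIII, start: 15800,  end: 17000,  kind: probe_locus}
  - {name: PAT1,   chrom: chrIII, start: 298000, end: 300000, kind: probe_locus}
  - {name: ARS310, chrom: chrIII, start: 166800, end: 167000, kind: replication_origin}
  - {name: ARS315, chrom: chrIII, start: 223000, end: 223200, kind: replication_origin}
  - {name: rDNA,   chrom: chrXII, start: 451000, end: 468000, kind: repeat_region}
snps:
  assays:
    - chrom: chrIII
      pos: 113543
      enzyme: MnlI
      amplicon: 462
      cut_fragments: [335, 127]
      cutting_allele: "Y"
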