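# Sixteen-strain LTGC fixture cohort.  Each strain records the repair
# mechanism, its breakpoints on chromosome III (S frame), signed junction
# repeat capture (positive: SNP-free repetitive sequence captured at the
# repair junction; negative: copied Ty content lost at the junction),
# chromosome-III-associated copy-number overlays, the gel separability of
# the two chromosome III homologs, and the strain's unselected genome-wide
# events (terminal LOH from canonical BIR / reciprocal crossover, some with
# an abrupt allele transition, CNVs, and short interior gene conversions).
cohort:
  name: "FS2 LTGC cohort"
  depth: 100
  snp_spacing: 300
  snp_jitter: 100
  panel_seed: 713
strains:
  - name: "LTGC 1"
    mechanism: dual_bir_ectopic
    invasion: 168000
    distal_end: 229001
    attach_chrom: chrII
    cha1_band: 550000
    pat1_band: 930000
    separable: true
    unselected:
      - {type: terminal, chrom: chrV, boundary: 355000, abrupt_switch: 470000}
      - {type: gene_conversion, chrom: chrX, start: 101000, end: 107000, origin: "Y"}
  - name: "LTGC 2"
    mechanism: late_template_switch
    invasion: 168000
    terminus: 210000
    capture: 8000
    chr3_cnv:
      - {interval: [128000, 168000], copy_state: 3}
    separable: true
    unselected:
      - {type: terminal, chrom: chrXII, boundary: 382000, abrupt_switch: 460000}
  - name: "LTGC 3"
    mechanism: dual_bir_ectopic
    invasion: 168000
    distal_end: 229001
    attach_chrom: chrXV
    cha1_band: 810000
    pat1_band: 1300000
    separable: true
    unselected:
      - {type: terminal, chrom: chrVII, boundary: 269000, origin: "Y"}
      - {type: terminal, chrom: chrXII, boundary: 455000, origin: "S"}
  - name: "LTGC 4"
    mechanism: half_crossover
    invasion: 168000
    cleavage: 245000
    capture: 12000
    separable: true
    unselected:
      - {type: cnv, chrom: chrII, interval: [221000, 224000], copy_state: 3}
      - {type: cnv, chrom: chrXV, interval: [849000, 851000], copy_state: 3}
  - name: "LTGC 5"
    mechanism: dual_bir_ectopic
    invasion: 168000
    distal_end: 229001
    attach_chrom: chrV
    cha1_band: 412000
    pat1_band: 780000
    separable: true
    unselected:
      - {type: terminal, chrom: chrXIV, boundary: 263000, origin: "S"}
      - {type: cnv, chrom: chrII, interval: [197000, 224000], copy_state: 3}
      - {type: gene_conversion, chrom: chrIV, start: 1333000, end: 1339000, origin: "S"}
  - name: "LTGC 6"
    mechanism: late_template_switch
    invasion: 160000
    terminus: 202000
    capture: -2000
    separable: true
    unselected: []
  - name: "LTGC 7"
    mechanism: late_template_switch
    invasion: 165000
    terminus: 250000
    capture: 0
    separable: true
    unselected: []
  - name: "LTGC 8"
    mechanism: half_crossover
    invasion: 155000
    cleavage: 242000
    capture: 5000
    chr3_cnv:
      - interval: [200000, 220000]
        copy_state: 1
        microhomology: {mh: 3, island: 2}
    separable: true
    unselected:
      - {type: terminal, chrom: chrXII, boundary: 599000, origin: "Y"}
      - {type: terminal, chrom: chrXV, boundary: 710000, abrupt_switch: 850000}
  - name: "LTGC 9"
    mechanism: half_crossover
    invasion: 156000
    cleavage: 242000
    capture: 33000
    separable: true
    unselected: []
  - name: "LTGC 10"
    mechanism: late_template_switch
    invasion: 162000
    terminus: 190000
    extra_tracts:
      - [205000, 248000]
    capture: -1000
    separable: true
    unselected:
      - {type: terminal, chrom: chrIV, boundary: 910000, origin: "S"}
      - {type: terminal, chrom: chrXIII, boundary: 165000, abrupt_switch: 100000}
      - {type: terminal, chrom: chrXVI, boundary: 416000, origin: "Y"}
      - {type: cnv, chrom: chrXV, interval: [849000, 851000], copy_state: 3}
      - {type: gene_conversion, chrom: chrIV, start: 378000, end: 413000, origin: "Y"}
  - name: "LTGC 11"
    mechanism: half_crossover
    invasion: 152000
    cleavage: 248000
    capture: 5000
    separable: false
    unselected:
      - {type: terminal, chrom: chrVIII, boundary: 387000, abrupt_switch: 470000}
      - {type: cnv, chrom: chrIV, interval: [1156000, 1164000], copy_state: 1}
      - {type: cnv, chrom: chrXII, interval: [599000, 651000], copy_state: 1}
  - name: "LTGC 12"
    mechanism: half_crossover
    invasion: 154000
    cleavage: 252000
    capture: -1000
    separable: false
    unselected:
      - {type: terminal, chrom: chrXII, boundary: 455000, origin: "S"}
      - {type: terminal, chrom: chrXVI, boundary: 929000, origin: "Y"}
  - name: "LTGC 13"
    mechanism: half_crossover
    invasion: 161000
    cleavage: 244000
    capture: 4000
    separable: true
    unselected:
      - {type: gene_conversion, chrom: chrXV, start: 628000, end: 634000, origin: "Y"}
  - name: "LTGC 14"
    mechanism: late_template_switch
    invasion: 157000
    terminus: 205000
    capture: 6000
    chr3_cnv:
      - {interval: [182000, 202000], copy_state: 1}
    separable: false
    unselected:
      - {type: terminal, chrom: chrXIII, boundary: 281000, origin: "S"}
      - {type: cnv, chrom: chrXV, interval: [849000, 851000], copy_state: 3}
  - name: "LTGC 15"
    mechanism: late_template_switch
    invasion: 163000
    terminus: 246000
    capture: 2000
    separable: true
    unselected:
      - {type: cnv, chrom: chrIV, interval: [1201000, 1212000], copy_state: 1}
  - name: "LTGC 16"
    mechanism: late_template_switch
    invasion: 159000
    terminus: 245000
    capture: 1000
    separable: true
    unselected:
      - {type: terminal, chrom: chrXIV, boundary: 345000, origin: "S"}
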