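# Default pipeline configuration: gene panel and variant retention thresholds.
# Thresholds are inclusive percentages.
panel:
  genes:
    - JAK2
    - TET2
    - DNMT3A
    - ASXL1
    - SRSF2
    - SF3B1
    - U2AF1
    - IDH1
    - IDH2
    - EZH2
    - NFE2
    - CBL
    - TP53
    - PPM1D
    - BCOR
filters:
  min_vaf: 2.0        # variant allele frequency floor, percent
  common_maf: 1.0     # common-polymorphism population MAF cutoff, percent
  rare_vus_maf: 0.01  # rare-polymorphism cutoff for VUS, percent
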