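n_genes: 17000
class_fractions:
  none: 0.851
  mendelian: 0.048
  gwas: 0.101
length_model:
  total_cds_meanlog: 7.0755842
  total_cds_sdlog: 0.6894
  class_mult_total_cds:
    none: 1.0
    mendelian: 1.28
    gwas: 1.44
  avg_ratio_base: 0.6
  avg_ratio_precision: 10.0
  class_mult_avg_cds:
    none: 1.0
    mendelian: 1.5
    gwas: 1.5
  intron_meanlog: 7.9121932
  intron_sdlog: 1.1
  class_mult_intron:
    none: 1.0
    mendelian: 1.0
    gwas: 1.0
  log_length_correlation: 0.48384
  introns_per_gene: 3.0
covariate_model:
  names:
  - GC content
  - Nucleosome occupancy
  - Female recombination rate
  - Male recombination rate
  - Germ-line expression
  - Replication time
  - Distance to telomere
  - Distance to centromere
  means:
    GC content: 0.45
    Nucleosome occupancy: 0.5
    Female recombination rate: 1.3
    Male recombination rate: 0.9
    Germ-line expression: 5.0
    Replication time: 0.0
    Distance to telomere: 40.0
    Distance to centromere: 60.0
  sds:
    GC content: 0.07
    Nucleosome occupancy: 0.1
    Female recombination rate: 0.9
    Male recombination rate: 0.6
    Germ-line expression: 2.0
    Replication time: 1.0
    Distance to telomere: 25.0
    Distance to centromere: 35.0
  correlation:
  - - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
rate_model:
  baseline_rate: 0.0034836
  coefficients:
    GC content: 0.3675
    Nucleosome occupancy: -0.2772
    Female recombination rate: -0.014
    Male recombination rate: 0.1414
    Germ-line expression: -0.0434
    Replication time: -0.0924
    Distance to telomere: -0.1106
    Distance to centromere: -0.0126
  cpg_multiplier: 10.0
  class_mult_divergence:
    none: 1.0
    mendelian: 0.95
    gwas: 0.95
diversity_model:
  class_mult_snp_density:
    none: 1.0
    mendelian: 1.11
    gwas: 1.17
  pi_over_div: 0.2
  genealogy_dispersion: 0.09
  maf_shape: 0.8
  maf_means:
    none: 0.1
    mendelian: 0.11
    gwas: 0.09
seq_model:
  intron_gc: 0.44
  cpg_density: 0.02
  cds_gc: 0.52
seed: 1
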