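# Example pipeline configuration for `scna-atlas all --config ...`
# Unset keys fall back to the defaults in default_config().
out_dir: scnatlas_out
seed: 1

# Either point at real inputs ...
# segments: path/to/cohort.seg
# genome: path/to/chrom.sizes
# arms: path/to/arms.tsv          # or a UCSC cytoBand file
# genes: path/to/census.bed
# annotations: path/to/annotations.tsv

# ... or simulate a cohort with planted truth:
simulate:
  enabled: true
  tumor_types: {OV: 50, BRCA: 50, SARC: 50, KIRC: 50, THCA: 50}
  planted_genes:
    - {gene: MYC, direction: AMP, tumor_type: ALL, frequency: 0.4}
    - {gene: CDKN2A, direction: DEL, tumor_type: ALL, frequency: 0.3}
  planted_pairs:
    - {gene_a: ERBB2, gene_b: MYC, event_type: AMP-AMP, frequency: 0.2}

params:
  amp_log2: 0.32
  del_log2: -0.42
  indel_max_bp: 10000
  arm_frac: 0.75
  gene_overlap_frac: 0.5

modes:
  chrom_norm: divide          # or "literal"
  gene_overlap_union: true
  include_classes: [SCNA]
  pair_min_frequency: 0.05
  top_genes_k: 25
  top_pairs_k: 100
  inter_chromosomal_only: true
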