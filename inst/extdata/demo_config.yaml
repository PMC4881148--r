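# Small five-family demo genome: 50 kb, ~50% planted repeats, one satellite
# strongly ChIP-enriched. Runs end to end in seconds.
simulate:
  seed: 101
  reads_seed: 11
  background_length: 25000
  coverage: 2
  read_length: 100
  insert_size: 300
  families:
    - {name: satA, kind: satellite, length: 60, copies: 150, divergence: 0.02}
    - {name: satB, kind: satellite, length: 80, copies: 75, divergence: 0.03}
    - {name: ltrA, kind: ltr_retrotransposon, length: 1000, copies: 5, divergence: 0.02}
    - {name: dtaA, kind: dna_transposon, length: 400, copies: 8, divergence: 0.02}
    - {name: plsA, kind: plastid_like, length: 600, copies: 3, divergence: 0.01}
  chip:
    seed: 22
    n_reads: 10000
    read_length: 50
    factors: {satA: 8}
cluster:
  min_identity: 90
  min_coverage: 0.55
  kmer_seed_length: 8
  min_links: 1
  proportion_threshold: 0.5
assemble:
  min_overlap: 31
annotate:
  min_identity: 80
  min_hit_length: 50
enrich:
  seed: 303
  n_sample: 3000
  trim_length: 50
  threshold: 1.5
  min_input: 20
  word_size: 9
report:
  estimated_genome_mb: 758
  assembly_mb: 567
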