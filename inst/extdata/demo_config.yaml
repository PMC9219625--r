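# Bundled three-species demonstration: spA and spC are close relatives, spB
# is the distant lineage; one recent horizontal transfer spA -> spB.
seed: 1
output_dir: "tehorizon-demo"
tree: "((spA:0.025,spC:0.025):0.225,spB:0.25);"
genome_length: 50000
gene_length: 4000
copies_per_species: 8
copy_age: 0.01
truncation_prob: 0.25
ht:
  - donor: "spA"
    recipient: "spB"
    time: 0.01
thresholds:
  identity: 0.70
  ratio_factor: 1.2
  alpha: 0.01
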