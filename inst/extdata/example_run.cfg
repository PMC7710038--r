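# Example: 20-position nucleotide sequence on a 4-leaf tree; positions 1-10
# under a stochastically fluctuating landscape, positions 11-20 under a
# landscape permuted at evenly spaced epochs shared across lineages.
tree = example_tree.nwk
alphabet = ACGT
scaling = normalized
seed = 42
replicates = 3
write_change_log = true
write_internal_nodes = true

[landscape]
positions = 1-10
init = lognormal mu=0 sigma=0.5
change_rule = resample
regime = stochastic lambda=1

[landscape]
positions = 11-20
init = gamma shape=2 scale=1
change_rule = permute
regime = periodic interval=0.5 sharing=shared
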