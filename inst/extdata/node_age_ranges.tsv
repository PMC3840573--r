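# Published divergence-time ranges (Mya) for nodes of mammal_dated_tree.nwk.
# The newick fixture stores one age per node: the younger (conservative) bound
# of the published range, so origination intervals report conservative values.
node	age_used	age_range_low	age_range_high
Theria	163.9	163.9	167.4
Simiiformes	42.6	42.6	65.2
Catarrhini	29.2	29.2	29.2
Hominoidea	20.6	20.6	20.6
Euarchontoglires	94.4	94.4	NA
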