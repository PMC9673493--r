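phylum	count
Firmicutes	278
Bacteroidota	25
Actinobacteriota	14
Other	20
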