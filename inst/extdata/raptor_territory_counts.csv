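species,n_territories
goshawk,29
sparrowhawk,57
buzzard,84
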