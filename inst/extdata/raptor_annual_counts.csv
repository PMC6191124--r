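species,year,n
goshawk,2004,22
goshawk,2005,20
goshawk,2006,20
goshawk,2007,18
goshawk,2008,18
goshawk,2009,18
goshawk,2010,18
goshawk,2011,19
sparrowhawk,2006,16
sparrowhawk,2007,22
sparrowhawk,2008,37
sparrowhawk,2009,26
sparrowhawk,2010,25
sparrowhawk,2011,24
buzzard,2004,29
buzzard,2005,26
buzzard,2006,28
buzzard,2007,39
buzzard,2008,32
buzzard,2009,34
buzzard,2010,42
buzzard,2011,30
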