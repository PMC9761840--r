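# binary mixture at the catfish equitoxic ratio
components: [atrazine, chlorpyrifos]
ratio: [33.95, 1.0]
species: catfish
stock_g_per_L: 3.495
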