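# choroidtrace CLI configuration (flat key=value; comma-separated vectors)
seed = 1
speckle = 0.3
vessels = 10
offsets = -2000, 0, 2000
threshold = 32
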