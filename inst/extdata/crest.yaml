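# CREST case-study scenario: prior estimated from the per-endpoint summary
# statistics of the screening series (composite of nine standardized
# endpoints, assumed inter-endpoint correlation 0.2).
m0: -0.067
v0: 0.165
delta: 0.25
alpha: 0.025
beta: 0.1
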