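{"A": [1, 4], "B": [2, 3], "C": [1, 1, 3]}
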