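gaitstab 0.1.0 | seed 1 | folds 5 repeats 5 a_max 5
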