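{"kind":"one_to_one","target":"LEU","source":"ILE","delta":0.1}
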