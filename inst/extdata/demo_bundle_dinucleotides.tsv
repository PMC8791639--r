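pos_i	base_i	pos_j	base_j	delta_e
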