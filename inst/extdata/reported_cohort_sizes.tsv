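group	n_trios	n_male
case	13	5
control	19	12
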