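seq_id	sprinzl_label	code
tRNA-Met-syn	47	acp3U
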