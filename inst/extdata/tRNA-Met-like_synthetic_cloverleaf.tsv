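seq_id	arm	start	end
tRNA-Met-syn	acceptor	0	9
tRNA-Met-syn	dArm	9	26
tRNA-Met-syn	acArm	26	43
tRNA-Met-syn	vLoop	43	48
tRNA-Met-syn	tArm	48	76
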