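start	end	delta_h	delta_a	delta_id
31	42	2	-0.3	-0.3
81	92	-1	0.3	0.2
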