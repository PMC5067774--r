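precursor_id	arm_name	start	end	template_context
syn-mir-1	syn-mir-1-5p	12	34	
syn-mir-1	syn-mir-1-3p	50	72	
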