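region_name	start	end
kinase	634	938
gene	1	950
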