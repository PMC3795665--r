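# coordinates are 1-based inclusive
name	start	end	coding
GENE1	21	60	TRUE
SPACER	61	100	FALSE
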