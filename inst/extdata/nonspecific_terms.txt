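biological_process
biological regulation
metabolic process
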