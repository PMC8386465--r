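name	ref_start	ref_end
V1-V9	28	1491
V3-V4	358	786
V4	534	786
V4-V5	534	908
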