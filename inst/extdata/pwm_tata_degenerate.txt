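>TATA_degenerate
0.35 0.15 0.15 0.35
0.40 0.10 0.10 0.40
0.30 0.15 0.15 0.40
0.45 0.08 0.07 0.40
0.42 0.10 0.08 0.40
0.35 0.15 0.10 0.40
0.40 0.12 0.13 0.35
0.30 0.20 0.20 0.30
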