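>TATA_strict
0.05 0.05 0.05 0.85
0.88 0.04 0.04 0.04
0.06 0.04 0.04 0.86
0.91 0.03 0.03 0.03
0.70 0.05 0.05 0.20
0.88 0.04 0.04 0.04
0.50 0.10 0.10 0.30
0.30 0.20 0.30 0.20
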