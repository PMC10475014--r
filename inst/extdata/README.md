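prc_linear_synthetic.csv: a SYNTHETIC, non-physiological linear phase
response curve (shift = -0.5 - 0.2*(phase - 2) hours on phase 1..5 h after
DLMO) used only to exercise the PRC-correction code paths in tests and
examples. Supply a published PRC table for real analyses.
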