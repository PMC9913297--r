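# Synthetic stand-in for the 21-gene stemness/chemoresistance target panel.
# The first 13 symbols are genuine pluripotency, stemness and ABC-transporter
# markers of spheroid-derived cancer stem-like cells; the trailing 8 entries
# are synthetic placeholders (no public drug-gene interactions are fabricated
# for them), so exactly 13/21 targets are druggable in the engineered bundle.
POU5F1
ABCB1
ABCC1
ABCG1
KIT
CAV1
ITGB1
CD44
DNMT3B
GABRB3
LIN28A
LEFTY2
PROM1
SYNTH14
SYNTH15
SYNTH16
SYNTH17
SYNTH18
SYNTH19
SYNTH20
SYNTH21
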