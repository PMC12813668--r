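# Default great cormorant (Phalacrocorax carbo sinensis) morphology:
# means of adult specimens. Muscle fractions in use: 0.103 (specimens),
# 0.136 (conspecific literature value), 0.17 (all-bird average).
mass_kg: 2.55
wingspan_m: 1.35
wing_area_m2: 0.224
muscle_fractions: [0.103, 0.136, 0.17]
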