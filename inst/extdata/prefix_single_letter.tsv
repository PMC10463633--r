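from	to
# single-letter prefixes that should be regrouped after truncation
# (mostly carbohydrate-modifying enzyme families); keys are the single
# letter remaining after digit replacement and truncation
B	B3GLYCO
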