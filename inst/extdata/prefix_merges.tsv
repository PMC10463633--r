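from	to
# family-level merges applied to derived prefixes
KCNT	KCN
KCNQ	KCN
KCNA	KCN
KCNB	KCN
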