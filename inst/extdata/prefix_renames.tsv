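from	to
# symbol-level renames (legacy symbol -> current nomenclature), applied
# before prefix derivation; edit or replace via prefix_overrides()
FAM46A	TENT5A
FAM46B	TENT5B
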