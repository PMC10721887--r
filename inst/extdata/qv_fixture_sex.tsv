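participant_id	sex
S_HET_F	female
S_COMPHET_F	female
S_HOM_F	female
S_HEMI_M	male
S_XHET_M	male
S_MASKED_F	female
S_REF_F	female
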