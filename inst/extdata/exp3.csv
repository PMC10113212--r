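condition,lineup_format,filler_type,cp_suspect,cp_filler,cp_reject,ca_suspect,ca_filler,ca_reject
sim_morphed,simultaneous,morphed,154,117,123,70,131,193
sim_nonmorphed,simultaneous,non-morphed,132,95,133,47,135,178
seq_morphed,sequential,morphed,116,208,66,53,235,102
seq_nonmorphed,sequential,non-morphed,126,184,66,58,220,98
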