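condition,lineup_format,filler_type,cp_suspect,cp_filler,cp_reject,ca_suspect,ca_filler,ca_reject
sim_morphed,simultaneous,morphed,135,86,145,49,119,198
sim_nonmorphed,simultaneous,non-morphed,144,119,137,55,139,206
seq_morphed,sequential,morphed,125,189,74,69,209,110
seq_nonmorphed,sequential,non-morphed,126,163,79,62,199,107
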