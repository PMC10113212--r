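condition,lineup_format,filler_type,cp_suspect,cp_filler,cp_reject,ca_suspect,ca_filler,ca_reject
sim_morphed,simultaneous,morphed,177,120,101,93,161,144
sim_nonmorphed,simultaneous,non-morphed,155,117,108,66,160,154
seq_morphed,sequential,morphed,112,220,60,58,247,87
seq_nonmorphed,sequential,non-morphed,130,201,65,67,234,95
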