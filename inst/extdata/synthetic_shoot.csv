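"reach_m","orientation_deg","EI_Nm2","d_v_m","d_h_m"
0.599865886214197,1.81489324111494,0.00619159978950308,0.00237969422596432,0.00237969422596432
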