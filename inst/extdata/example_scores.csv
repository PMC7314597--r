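participant_id,forward_digit,dot_matrix,backward_digit,mr_x,timepoint,gf_score
child_01,95.5,102,88.25,110,pre,104
child_02,81,79.5,90,85.75,pre,92
child_03,120,111.5,105,99.25,pre,118
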