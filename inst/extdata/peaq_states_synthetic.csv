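molecule_id,state_label,g_aq_hartree
2_2PEAQ_synthetic,QH2,-920.000000000000
2_2PEAQ_synthetic,QH2+,-919.879300909881
2_2PEAQ_synthetic,QH2^2+,-919.711577375362
2_2PEAQ_synthetic,QH-,-919.508703026606
2_2PEAQ_synthetic,QH,-919.427935761600
2_2PEAQ_synthetic,QH+,-919.291270313280
2_2PEAQ_synthetic,Q^2-,-918.995221705928
2_2PEAQ_synthetic,Q-,-918.949949396577
2_2PEAQ_synthetic,Q,-918.848778903913
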