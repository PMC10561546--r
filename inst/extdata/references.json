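{"g_h2_gas":-1.17,"ref_acid_g_ha":-189.75,"ref_acid_g_a":-189.271803771052,"pka_ref":3.77}
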