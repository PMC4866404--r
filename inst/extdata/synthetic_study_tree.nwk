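((((C_aspersum:0.030,(C_nemoralis:0.012,C_hortensis:0.012):0.020):0.008,A_arbustorum:0.038):0.006,((H_pomatia:0.010,H_lucorum:0.010):0.022,(T_pisana:0.024,E_vermiculata:0.024):0.008):0.012):0.030,F_fruticum:0.074);
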