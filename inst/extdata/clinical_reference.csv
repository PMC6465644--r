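sample_id,age_band,subtype,pct_blasts,platelets_k_ul,leukocytes_k_ul,cytogenetics,risk,remission,dispersion
LPZ6,76-80,M4,16,42,16,Complex,adverse,no,random
LPZ10,76-80,M4Eos,42,282,2.2,Normal,intermediate,NA,clumped
LPZ12,40-45,M3,2,35,2,t(15;17),favorable,yes,clumped
LPZ13,30-35,M1,84.6,207,90,Normal,intermediate,no,clumped
LPZ15,40-45,M5B,6,29,104.9,"47,XY,+6",intermediate,no,random
LPZ14,30-35,ALL-B,91.34,26,5.7,Normal,standard,yes,clumped
LPZ21,46-50,ALL-B,76,231,67.4,"47,XXY,t(9;22)",adverse,no,random
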