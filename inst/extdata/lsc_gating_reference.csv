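sample_id,lineage,aldh_pattern,pct_aldh_bright_ssclow,pct_cd34_within,pct_lsc_combined_reported
LPZ6,AML,numerous,25.6,51.1,13.08
LPZ12,AML,rare,0.27,11.3,0.03
LPZ13,AML,numerous,37.9,45.6,17.28
LPZ15,AML,rare,1.58,29.7,0.47
LPZ14,ALL,rare,1.74,68,1.18
LPZ21,ALL,numerous,24.96,24.83,23.78
K562,cell-line,numerous,31.3,0.19,0.06
U937,cell-line,rare,0.96,26.4,0.25
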