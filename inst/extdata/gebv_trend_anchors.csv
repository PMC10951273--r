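trait,cp_year,start_year,end_year,y_start,y_cp,y_end
yield,1961,1775,2015,467.71,450.94,680.56
count,1893,1775,2015,21.52,21.31,23.80
weight,1971,1775,2015,20.86,20.12,29.74
firmness,1969,1775,2015,0.58,0.54,0.81
tss,1969,1775,2015,9.81,9.86,9.21
ta,1978,1775,2015,0.89,0.89,0.77
tss_ta,1976,1775,2015,11.31,11.22,11.91
anthocyanin,1959,1775,2015,117.84,120.45,107.13
vw_score,1957,1775,2015,2.49,2.44,2.84
vw_audps,1956,1775,2015,10.92,10.92,11.89
phcr_score,1953,1775,2015,3.00,2.94,3.15
phcr_audps,1952,1775,2015,30.39,29.92,32.14
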