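endpoint,criteria,tg_source,prevalence_percent,n_reported
high_ldl,ldl_ge_3,visit2,56.4,4282
high_ldl,ldl_ge_3,visit1_raw,51.3,4282
high_ldl,ldl_ge_3,visit1_corrected,54.8,4282
mets,atp,visit2,35.5,4282
mets,atp,visit1_raw,39.7,4282
mets,atp,visit1_corrected,37.6,4282
mets,idf,visit2,44.8,4282
mets,idf,visit1_raw,47.1,4282
mets,idf,visit1_corrected,45.6,4282
mets,idftf,visit2,46.3,4282
mets,idftf,visit1_raw,49.8,4282
mets,idftf,visit1_corrected,47.9,4282
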