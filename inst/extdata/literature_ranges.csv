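component,source,value_low,value_high,kind
cellulose,leaf_sheaths,22.04,22.66,mean_pm_sd
cellulose,trunks,41.29,47.21,mean_pm_sd
cellulose,fruit_bunch,40.13,40.87,mean_pm_sd
cellulose,mesocarp,32.00,60.00,range
hemicellulose,leaf_sheaths,38.50,44.10,mean_pm_sd
hemicellulose,trunks,32.69,35.19,mean_pm_sd
hemicellulose,fruit_bunch,24.16,24.44,mean_pm_sd
hemicellulose,mesocarp,9.80,31.00,range
lignin,leaf_sheaths,33.46,39.24,mean_pm_sd
lignin,trunks,30.96,35.28,mean_pm_sd
lignin,fruit_bunch,35.09,35.31,mean_pm_sd
lignin,mesocarp,11.00,32.80,range
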