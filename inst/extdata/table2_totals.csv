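year,total
2015,NA
2016,35
2017,32
2018,25
2019,19
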