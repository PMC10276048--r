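outcome,seatbelt,period,male,slope,rors
1,restrained,2012-2013,1,0,0
2,restrained,2012-2013,1,1,0
1,unrestrained,2012-2013,0,0,1
3,unrestrained,2012-2013,1,0,1
1,restrained,2014-2015,1,0,0
2,unrestrained,2014-2015,0,1,0
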