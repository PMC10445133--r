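stratification,stratum,a,b,c,d
scratch,infrequent,2293,26414,673,17666
scratch,occasional,2281,33995,2559,54360
scratch,elevated,1543,18812,1819,31038
scratch,severe,863,7016,331,5084
lick,infrequent,665,10476,178,5944
lick,occasional,2790,37938,2735,57768
lick,elevated,2446,28938,2303,41984
lick,severe,1079,8885,166,2452
combined,combined,6980,86237,5382,108148
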