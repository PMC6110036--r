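group,d_plus,d_minus,c_published,rank_published
model,0.502,0,0,8
atorvastatin,0.045,0.465,0.912,2
angelica,0.106,0.396,0.789,5
astragalus,0.340,0.164,0.325,7
aa-1:2,0.085,0.417,0.831,3
aa-1:5,0.086,0.417,0.829,4
aa-1:1,0,0.502,1,1
aa-5:1,0.128,0.375,0.746,6
aa-2:1,0.340,0.164,0.325,7
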