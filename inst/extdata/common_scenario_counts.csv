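scenario_id,code,n_s,n_mda,n_sda,pr_printed
1,[11111],21,0,0,1.000
5,[11122],17,4,0,0.676
11,[11212],14,7,0,0.533
59,[13122],1,9,11,0.433
92,[21212],4,16,1,0.600
122,[22222],1,17,3,0.662
166,[31121],2,8,11,0.400
203,[32222],1,3,17,0.662
230,[33222],1,0,20,0.905
243,[33333],0,0,21,1.000
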