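group,n_pairs,rejection_rate
all_resettled,86,0.07
all_traditional,31,0.10
mupfurudzi_all,64,0.09
mutanda_resettled,9,0.00
mutanda_traditional,10,0.10
sengezi_resettled,25,0.04
sengezi_traditional,9,0.11
pooled_all,117,0.08
mutanda_all,19,0.05
sengezi_all,34,0.06
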