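group,area,status,offer,n,rejection_rate
all_resettled,all,resettled,0.1,2,0.50
all_resettled,all,resettled,0.2,5,0.60
all_resettled,all,resettled,0.3,3,0.00
all_resettled,all,resettled,0.4,14,0.14
all_resettled,all,resettled,0.5,59,0.00
all_resettled,all,resettled,0.6,3,0.00
all_traditional,all,traditional,0.0,1,0.00
all_traditional,all,traditional,0.1,1,1.00
all_traditional,all,traditional,0.2,4,0.25
all_traditional,all,traditional,0.4,8,0.13
all_traditional,all,traditional,0.5,17,0.00
mupfurudzi_all,mupfurudzi,all,0.1,3,0.67
mupfurudzi_all,mupfurudzi,all,0.2,5,0.40
mupfurudzi_all,mupfurudzi,all,0.3,2,0.00
mupfurudzi_all,mupfurudzi,all,0.4,11,0.18
mupfurudzi_all,mupfurudzi,all,0.5,40,0.00
mupfurudzi_all,mupfurudzi,all,0.6,3,0.00
mutanda_resettled,mutanda,resettled,0.4,2,0.00
mutanda_resettled,mutanda,resettled,0.5,7,0.00
mutanda_traditional,mutanda,traditional,0.2,2,0.50
mutanda_traditional,mutanda,traditional,0.4,1,0.00
mutanda_traditional,mutanda,traditional,0.5,7,0.00
sengezi_resettled,sengezi,resettled,0.2,1,1.00
sengezi_resettled,sengezi,resettled,0.3,1,0.00
sengezi_resettled,sengezi,resettled,0.4,5,0.00
sengezi_resettled,sengezi,resettled,0.5,18,0.00
sengezi_traditional,sengezi,traditional,0.0,1,0.00
sengezi_traditional,sengezi,traditional,0.2,1,0.00
sengezi_traditional,sengezi,traditional,0.4,3,0.33
sengezi_traditional,sengezi,traditional,0.5,4,0.00
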