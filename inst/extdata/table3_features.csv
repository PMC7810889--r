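feature_id,reference,mz,rt
6956,NT10,358.3,11.97
4225,NR10,349.2,10.22
8738,TLU,256.3,11.43
8776,TLU,270.3,11.49
8791,TLU,312.3,11.38
8813,TLU,151.0,0.82
1739,DWR,337.2,11.29
809,APE,339.2,11.71
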