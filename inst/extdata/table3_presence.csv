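vessel,6956,4225,8738,8776,8791,8813,1739,809
V01,X,,X,,,,,
V02,X,,X,,,X,,
V03,X,,X,,,X,,
V04,,,X,,,,,
V05,,,X,,,,,
V06,,,X,,,X,,
V07,,,,,,,,
V08,X,,X,,,X,,
V09,X,,X,,,,X,
V10,,,X,,,,,X
V11,X,,,X,,,,
V12,,,,,X,,X,
V13,X,,X,X,X,X,,X
V14,,X,,,,X,,
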