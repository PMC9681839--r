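version,test1,test2,test3,test4,test5,reported_mean,reported_std
slim,0.7581,0.7543,0.7301,0.7196,0.6696,0.7263,0.032
brightfield,0.8476,0.8545,0.8544,0.8736,0.8112,0.848,0.02
translated,0.7742,0.7805,0.6877,0.7569,0.7363,0.7469,0.03
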