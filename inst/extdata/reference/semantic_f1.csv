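version,test1,test2,test3,test4,test5,reported_mean,reported_std
slim,0.785,0.769,0.749,0.762,0.709,0.7548,0.026
brightfield,0.81,0.819,0.82,0.831,0.796,0.8152,0.012
translated,0.796,0.81,0.749,0.742,0.735,0.7664,0.031
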