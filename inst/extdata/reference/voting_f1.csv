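version,background,neutrophil,eosinophil,lymphocyte,monocyte,reported_average
slim,0.996,0.716,0.925,0.591,0.701,0.786
brightfield,0.997,0.755,0.901,0.696,0.797,0.829
translated,0.997,0.685,0.867,0.685,0.757,0.798
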