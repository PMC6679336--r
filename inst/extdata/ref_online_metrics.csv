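class,accuracy,specificity,recall,precision,fscore
walking,92.93,98.85,17.58,54.46,26.58
standing,56.49,85.07,40.29,82.64,54.17
lying,59.06,44.74,94.28,40.95,57.10
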