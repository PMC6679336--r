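class,accuracy,specificity,recall,precision,fscore
walking,92.93,98.87,17.22,54.56,26.18
standing,78.35,58.16,89.79,79.11,84.11
lying,84.25,91.48,66.45,76.03,70.92
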