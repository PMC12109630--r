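cohort,row,accuracy,sensitivity,specificity,ppv,npv,f1
patch128,1,87.6,91.1,84.6,83.3,91.8,87.0
patch128,2,88.7,70.3,95.1,83.1,90.3,76.2
patch128,3,90.3,15.5,98.3,49.9,91.6,23.6
patch128,average,88.8,58.9,92.6,72.1,91.2,62.3
best3,1,94.9,93.1,96.2,95.1,94.7,94.1
best3,2,92.6,95.3,85.6,94.5,87.5,94.9
best3,3,94.8,98.6,81.8,94.9,94.4,96.7
best3,average,94.1,95.7,87.8,94.8,92.2,95.2
worst3,1,91.1,87.1,93.9,91.0,91.1,89.0
worst3,2,89.4,88.4,91.5,95.7,78.8,91.9
worst3,3,92.1,83.7,96.7,93.1,91.7,88.1
worst3,average,90.9,86.4,94.0,93.3,87.2,89.7
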