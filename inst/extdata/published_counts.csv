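cohort,biopsies,nuclei,gland_nuclei
train,66,646426,213702
validation,22,210982,60310
test,22,407364,175867
total,110,1264772,449879
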