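patient_id,gene,subtype,vaf
EX01,NPM1,typeA,0.44
EX01,FLT3,ITD,0.12
EX02,DNMT3A,R882,0.47
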