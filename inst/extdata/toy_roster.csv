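id,group,gender,wave1,wave2
s1,A,F,TRUE,TRUE
s2,A,M,TRUE,TRUE
s3,A,F,TRUE,TRUE
s4,B,M,TRUE,TRUE
s5,B,F,TRUE,TRUE
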