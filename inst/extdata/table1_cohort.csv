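id,age,sex,ms_subtype,initial_target,side,baseline_trs_motor,improvement_3m,improvement_6m
1,30,F,relapsing-remitting,VIM,left,37,,
2,27,M,relapsing-remitting,VIM,left,43,,
3,49,F,relapsing-remitting,VOp,left,30,,
4,54,F,primary-progressive,VOp,right,34,,
5,47,F,relapsing-remitting,VIM,left,49,,
6,51,F,relapsing-remitting,VOp,left,41,,
7,36,F,relapsing-remitting,VIM,left,50,,
8,58,F,relapsing-remitting,VIM,left,26,,
9,23,F,primary-progressive,VIM,left,34,,
10,40,F,relapsing-remitting,VOp,right,42,,
11,72,F,primary-progressive,VOp,left,58,,
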