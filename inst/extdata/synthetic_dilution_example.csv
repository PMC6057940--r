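dose,tested,responded,group
50,10,1,ctrl
200,10,4,ctrl
800,10,6,ctrl
3200,10,9,ctrl
50,10,1,hh
200,10,6,hh
800,10,10,hh
3200,10,10,hh
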