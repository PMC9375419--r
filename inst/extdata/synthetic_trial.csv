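cluster,arm,events,size
c01,0,0,10
c02,0,5,20
c03,0,3,13
c04,0,8,24
c05,0,10,32
c06,0,12,29
c07,1,6,13
c08,1,9,27
c09,1,16,36
c10,1,15,37
c11,1,8,23
c12,1,8,13
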