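class,safflower,turmeric,red40,yellow5,pure
safflower,50,0,0,0,0
turmeric,1,49,0,0,0
red40,0,0,50,0,0
yellow5,0,0,0,50,0
pure,0,0,0,0,10
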