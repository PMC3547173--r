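,width,v1_size,a23,f
width,1,0.364,-0.32,0.271
v1_size,0.364,1,-0.099,0.286
a23,-0.32,-0.099,1,-0.379
f,0.271,0.286,-0.379,1
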