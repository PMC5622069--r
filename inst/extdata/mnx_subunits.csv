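name,label,mass,min_copies,max_copies
MnxG,G,139000,0,1
MnxE,E,12000,0,8
MnxF,F,12000,0,8
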