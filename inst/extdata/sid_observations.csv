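composition,class
E1,minor
F1,minor
E1F1,major
E1F2,major
E2F1,minor
E2F2,major
E2F3,major
E3F3,major
F2,trace
E1F3,trace
E2,absent
E3,absent
F3,absent
E3F1,absent
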