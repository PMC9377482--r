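name,version,constructor
sepsis3,1.0,sepsis3_engine
edtriage,1.0,edtriage_engine
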