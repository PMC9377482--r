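component,variable,operator,threshold
low_sbp,sbp,le,100
high_resp_rate,resp_rate,ge,22
altered_mentation,gcs,lt,15
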