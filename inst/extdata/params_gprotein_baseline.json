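{"kRL":0.002,"kRLm":0.01,"kRs":4,"kRd0":0.0004,"kRd1":0.0004,"kGa":1e-05,"kGd":0.1,"kG1":1,"Gt":10000}
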