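{"DR":0.001,"DRL":0.001,"DG":0.01,"DGa":0.01,"DGbg":0.01,"DGd":0.01,"DC24m":0.01,"DC42":0.01,"DC42a":0.01,"DB1m":0.01,"kRL":0.002,"kRLm":0.01,"kRd0":0.0004,"kRd1":0.0004,"kRs":0.318309886183791,"kGa":0.000125663706143592,"kGd":0.1,"kG1":1,"k42d":0.02,"k42a":0.000125663706143592,"k24cm0":0.04,"k24cm1":0.0414690230273853,"k24mc":1,"kB1mc":0.01,"kB1cm":0.000125663706143592,"kCla4a":0.006,"kCla4d":0.01,"k24d":0.00418879020478639,"q":100,"h":8,"C24t":2000,"B1t":3000,"Rt":10000,"Gt":10000,"C42t":10000}
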