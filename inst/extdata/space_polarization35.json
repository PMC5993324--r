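[{"name":"DR","lo":0.0009,"hi":0.0011,"scale":"log10"},{"name":"DRL","lo":0.0009,"hi":0.0011,"scale":"log10"},{"name":"DG","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DGa","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DGbg","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DGd","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DC24m","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DC42","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DC42a","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DB1m","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"kRL","lo":0.0018,"hi":0.0022,"scale":"log10"},{"name":"kRLm","lo":0.009,"hi":0.011,"scale":"log10"},{"name":"kRd0","lo":0.00036,"hi":0.00044,"scale":"log10"},{"name":"kRd1","lo":0.00036,"hi":0.00044,"scale":"log10"},{"name":"kRs","lo":0.286478897565412,"hi":0.35014087480217,"scale":"log10"},{"name":"kGa","lo":0.000113097335529233,"hi":0.000138230076757951,"scale":"log10"},{"name":"kGd","lo":0.09,"hi":0.11,"scale":"log10"},{"name":"kG1","lo":0.9,"hi":1.1,"scale":"log10"},{"name":"k42d","lo":0.02,"hi":2,"scale":"log10"},{"name":"k42a","lo":0.000125663706143592,"hi":0.0125663706143592,"scale":"log10"},{"name":"k24cm0","lo":0.004,"hi":0.4,"scale":"log10"},{"name":"k24cm1","lo":0.00414690230273853,"hi":0.414690230273853,"scale":"log10"},{"name":"k24mc","lo":0.1,"hi":1,"scale":"log10"},{"name":"kB1mc","lo":0.01,"hi":1,"scale":"log10"},{"name":"kB1cm","lo":0.000125663706143592,"hi":0.0125663706143592,"scale":"log10"},{"name":"kCla4a","lo":0.0006,"hi":0.06,"scale":"log10"},{"name":"kCla4d","lo":0.001,"hi":0.1,"scale":"log10"},{"name":"k24d","lo":0.000418879020478639,"hi":0.0418879020478639,"scale":"log10"},{"name":"q","lo":1,"hi":100,"scale":"linear"},{"name":"h","lo":1,"hi":8,"scale":"linear"},{"name":"C24t","lo":1000,"hi":3000,"scale":"log10"},{"name":"B1t","lo":2000,"hi":5000,"scale":"log10"},{"name":"Rt","lo":9000,"hi":11000,"scale":"log10"},{"name":"Gt","lo":9000,"hi":11000,"scale":"log10"},{"name":"C42t","lo":5000,"hi":20000,"scale":"log10"}]
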