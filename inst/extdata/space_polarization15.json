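[{"name":"k42a","lo":0.000125663706143592,"hi":0.0125663706143592,"scale":"log10"},{"name":"k42d","lo":0.02,"hi":2,"scale":"log10"},{"name":"DC42","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"DC42a","lo":0.005,"hi":0.02,"scale":"log10"},{"name":"q","lo":1,"hi":100,"scale":"linear"},{"name":"h","lo":1,"hi":8,"scale":"linear"},{"name":"k24cm1","lo":0.00414690230273853,"hi":0.414690230273853,"scale":"log10"},{"name":"kB1cm","lo":0.000125663706143592,"hi":0.0125663706143592,"scale":"log10"},{"name":"kB1mc","lo":0.01,"hi":1,"scale":"log10"},{"name":"C24t","lo":1000,"hi":3000,"scale":"log10"},{"name":"B1t","lo":2000,"hi":5000,"scale":"log10"},{"name":"kCla4a","lo":0.0006,"hi":0.06,"scale":"log10"},{"name":"kCla4d","lo":0.001,"hi":0.1,"scale":"log10"},{"name":"k24cm0","lo":0.004,"hi":0.4,"scale":"log10"},{"name":"k24d","lo":0.000418879020478639,"hi":0.0418879020478639,"scale":"log10"}]
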