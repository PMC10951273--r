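region,variable,b0,b1
us,production_kg,-4.355e10,2.222e7
europe,production_kg,-5.233e10,2.678e7
us,yield_kg_ha,-2032000,1037
europe,yield_kg_ha,14081,-1.5
us,area_ha,149786,-64.8
europe,area_ha,-4157095,2136
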