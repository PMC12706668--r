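"criterion","criterion_weight","indicator","label","local_weight","comprehensive_weight","rank"
"A",0.14286,"A1","Attractive and friendly form",0.42857,0.0614,7
"A",0.14286,"A2","Humanistic care",0.14286,0.0204,12
"A",0.14286,"A3","Comfortable human-machine dimensions",0.42857,0.0614,6
"M",0.28571,"M1","Structural stability",0.5,0.1429,3
"M",0.28571,"M2","Safety protection",0.25,0.0714,5
"M",0.28571,"M3","Anti-slip features",0.125,0.0357,9
"M",0.28571,"M4","Brake mechanism",0.125,0.0357,10
"O",0.57143,"O1","Foldability",0.04205,0.024,11
"O",0.57143,"O2","Ease of use",0.19738,0.1131,4
"O",0.57143,"O3","Adjustable size",0.07881,0.045,8
"O",0.57143,"O4","Adjustable safety guardrail",0.3676,0.2098,1
"O",0.57143,"O5","Flexible movement",0.28554,0.1637,2
"O",0.57143,"O6","Compact and lightweight",0.02862,0.0164,13
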