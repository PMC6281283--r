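Surface,Material,Radius,Thickness,Conic,alpha2,alpha3
Obj,air,infinity,32.6,,,
1,OKP4HT,-20.585,5.0,12.222,-3.086e-4,8.902e-7
2,PMMA,9.862,3.5,,,
STOP,air,-20.904,19.0,15.340,-5.511e-5,5.041e-6
4,PMMA,46.623,8.0,11.035,-4.636e-5,-8.567e-8
5,air,-20.564,89.0,-1.795,-2.443e-5,-5.850e-8
6,PMMA,33.722,12.0,4.506,5.408e-5,1.450e-7
7,air,-7.986,0.0,-4.612,7.972e-5,4.231e-7
8,OKP4HT,10.437,6.0,0.397,3.454e-5,1.445e-6
9,air,4.480,8.0,-3.363,4.041e-4,1.126e-5
10,smartphone camera,,,,,
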