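sex,age_months,L,M,S
male,72,-1.5,15.3,0.1
male,78,-1.5,15.529166666666667,0.1
male,84,-1.5,15.758333333333335,0.1
male,90,-1.5,15.9875,0.1
male,96,-1.5,16.21666666666667,0.1
male,102,-1.5,16.445833333333333,0.1
male,108,-1.5,16.675,0.1
male,114,-1.5,16.90416666666667,0.1
male,120,-1.5,17.133333333333333,0.1
male,126,-1.5,17.3625,0.1
male,132,-1.5,17.59166666666667,0.1
male,138,-1.5,17.820833333333333,0.1
male,144,-1.5,18.05,0.1
male,150,-1.5,18.27916666666667,0.1
male,156,-1.5,18.508333333333333,0.1
male,162,-1.5,18.7375,0.1
male,168,-1.5,18.96666666666667,0.1
male,174,-1.5,19.195833333333333,0.1
male,180,-1.5,19.425,0.1
male,186,-1.5,19.65416666666667,0.1
male,192,-1.5,19.883333333333333,0.1
male,198,-1.5,20.1125,0.1
male,204,-1.5,20.34166666666667,0.1
male,210,-1.5,20.570833333333333,0.1
male,216,-1.5,20.8,0.1
female,72,-1.5,15.1,0.1
female,78,-1.5,15.329166666666666,0.1
female,84,-1.5,15.558333333333334,0.1
female,90,-1.5,15.7875,0.1
female,96,-1.5,16.016666666666666,0.1
female,102,-1.5,16.245833333333334,0.1
female,108,-1.5,16.475,0.1
female,114,-1.5,16.704166666666666,0.1
female,120,-1.5,16.933333333333334,0.1
female,126,-1.5,17.1625,0.1
female,132,-1.5,17.391666666666666,0.1
female,138,-1.5,17.620833333333334,0.1
female,144,-1.5,17.85,0.1
female,150,-1.5,18.079166666666666,0.1
female,156,-1.5,18.308333333333334,0.1
female,162,-1.5,18.5375,0.1
female,168,-1.5,18.766666666666666,0.1
female,174,-1.5,18.995833333333334,0.1
female,180,-1.5,19.225,0.1
female,186,-1.5,19.454166666666666,0.1
female,192,-1.5,19.683333333333334,0.1
female,198,-1.5,19.9125,0.1
female,204,-1.5,20.141666666666666,0.1
female,210,-1.5,20.370833333333334,0.1
female,216,-1.5,20.6,0.1
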