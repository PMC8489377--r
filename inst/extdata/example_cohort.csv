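ID,TIME,EVID,AMT,DUR,DV,MDV,KIND,GROUP,WT,HT,SCR,AGE,PRETERM,SEX,ALT,AST,BUN,CYSC,ALB,TP,COMED,EGFR
1,0,1,62.7784598029246,1,,1,,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,6,1,62.7784598029246,1,,1,,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,12,1,62.7784598029246,1,,1,,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,18,1,62.7784598029246,1,,1,,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,23.5,0,,,2.96547421271105,0,trough,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,24,1,62.7784598029246,1,,1,,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,25.5,0,,,7.6340152964922,0,peak,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
1,30,1,62.7784598029246,1,,1,,augmented,6.27784598029246,66.9578700010453,19.2298714555325,2,0,0,116.069214991407,38.1974435530495,1.53731957661022,0.51028218731986,44.0899872478726,72.0368053335037,1,138.512837945948
2,0,1,28.6488090764321,1,,1,,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,6,1,28.6488090764321,1,,1,,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,12,1,28.6488090764321,1,,1,,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,18,1,28.6488090764321,1,,1,,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,23.5,0,,,4.14891940000802,0,trough,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,24,1,28.6488090764321,1,,1,,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,25.5,0,,,11.0049981525613,0,peak,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
2,30,1,28.6488090764321,1,,1,,augmented,2.86488090764321,44.2836148095267,16.3553109462696,1,0,1,174.344280934878,44.7591148179574,7.65812733902003,1.39906005733687,44.0186468293203,72.0565105355567,1,107.70826692994
3,0,1,56.0582882688909,1,,1,,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,6,1,56.0582882688909,1,,1,,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,12,1,56.0582882688909,1,,1,,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,18,1,56.0582882688909,1,,1,,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,23.5,0,,,4.15799349604363,0,trough,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,24,1,56.0582882688909,1,,1,,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,25.5,0,,,12.3506364834097,0,peak,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
3,30,1,56.0582882688909,1,,1,,augmented,5.60582882688909,58.1138931398923,19.4270211970619,1,0,0,11.5313119235862,107.362954047502,6.27567428004684,1.15128251709234,44.0818869425987,71.9037089349093,0,118.997691187702
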