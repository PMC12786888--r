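zone,feature,timepoint,median
left_cheek,contrast,T0,7.52
left_cheek,contrast,T1,6.20
left_cheek,contrast,T2,6.20
right_cheek,contrast,T0,7.46
right_cheek,contrast,T1,6.16
right_cheek,contrast,T2,6.17
nose,contrast,T0,6.86
nose,contrast,T1,5.95
nose,contrast,T2,5.92
chin,contrast,T0,6.92
chin,contrast,T1,5.95
chin,contrast,T2,5.73
face,contrast,T0,7.28
face,contrast,T1,6.02
face,contrast,T2,6.03
left_cheek,homogeneity,T0,0.488
left_cheek,homogeneity,T1,0.511
left_cheek,homogeneity,T2,0.510
right_cheek,homogeneity,T0,0.482
right_cheek,homogeneity,T1,0.499
right_cheek,homogeneity,T2,0.506
nose,homogeneity,T0,0.496
nose,homogeneity,T1,0.518
nose,homogeneity,T2,0.518
chin,homogeneity,T0,0.488
chin,homogeneity,T1,0.506
chin,homogeneity,T2,0.510
face,homogeneity,T0,0.490
face,homogeneity,T1,0.512
face,homogeneity,T2,0.511
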