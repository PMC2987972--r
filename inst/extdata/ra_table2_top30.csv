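icd9,description,n_case,N_case,printed_pct,printed_rr,printed_ci_low,printed_ci_high
6960,Psoriatic arthropathy,1540,61591,2.5,12.3,10.5,15.1
99529,Adverse effect medicinal and biologic substance NEC/NOS,360,61591,0.6,7.7,5.7,10.4
99666,Reaction-internal joint prosthesis,131,61591,0.2,4.0,2.7,5.8
9952,Unspecified adverse effect drug properly administered,717,61591,1.2,3.9,3.4,4.7
73309,Osteoporosis NEC,479,61591,0.8,3.9,3.2,4.8
5163,Idiopathic fibrosing alveolitis,205,61591,0.3,3.9,2.9,5.2
73027,Osteomyelitis NOS-ankle,148,61591,0.2,3.5,2.5,5.0
2793,Immunity deficiency NOS,81,61591,0.1,3.4,2.1,5.3
7901,Elevated sediment rate,171,61591,0.3,3.3,2.4,4.5
7955,Tuberculin test reaction abnormal or positive,239,61591,0.4,3.3,2.5,4.3
99520,Adverse effect medicinal and biologic substance NOS,708,61591,1.1,3.2,2.8,3.8
73020,Osteomyelitis NOS-unspec,119,61591,0.2,3.1,2.2,4.5
28529,Anemia-of other chronic illness,415,61591,0.7,3.1,2.6,3.8
2550,Cushing's syndrome,61,61591,0.1,3.0,1.8,5.1
515,Postinflammatory pulmonary fibrosis,1221,61591,2.0,3.0,2.7,3.4
2841,Pancytopenia,80,61591,0.1,3.0,1.9,4.6
4920,Emphysematous BLEB,72,61591,0.1,2.9,1.8,4.5
79579,Other and unspecified nonspecific immunologic findings,373,61591,0.6,2.8,2.3,3.5
2794,Autoimmune disease NEC,142,61591,0.2,2.8,2.1,3.9
5369,Stomach function disorder NOS,67,61591,0.1,2.8,1.8,4.4
4430,Raynaud's syndrome,251,61591,0.4,2.8,2.2,3.5
53130,Acute stomach ulcer NOS,76,61591,0.1,2.7,1.8,4.2
70709,Decubitus ulcer site NEC,97,61591,0.2,2.7,1.8,4.0
8082,Fracture of pubis-closed,136,61591,0.2,2.7,1.9,3.7
27549,Disorders of calcium metabolism NEC,69,61591,0.1,2.6,1.7,4.2
73340,Aseptic necrosis bone NOS,75,61591,0.1,2.6,1.7,4.0
8088,Pelvic fracture NOS-closed,121,61591,0.2,2.6,1.8,3.6
73007,Acute osteomyelitis-ankle,77,61591,0.1,2.6,1.7,3.9
4476,Arteritis NOS,247,61591,0.4,2.5,2.0,3.2
73302,Idiopathic osteoporosis,182,61591,0.3,2.5,1.9,3.3
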