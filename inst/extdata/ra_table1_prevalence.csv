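icd9,description,n_case,N_case,printed_pct
4019,Hypertension NOS,12773,62681,20.4
4011,Benign hypertension,12482,62681,19.9
78650,Chest pain NOS,8742,62681,13.9
2724,Hyperlipidemia NEC/NOS,8690,62681,13.9
25000,Diabetes Mellitus II without complication,7504,62681,12.0
78079,Malaise & fatigue NEC,6046,62681,9.6
5990,Urinary tract infection NOS,5965,62681,9.5
78900,Abdominal pain unspecified site,5712,62681,9.1
7862,Cough,5649,62681,9.0
2449,Hypothyroidism NOS,5524,62681,8.8
78605,Shortness of breath,5516,62681,8.8
4660,Acute bronchitis,5400,62681,8.6
2720,Pure hypercholesterolemia,5046,62681,8.1
4619,Acute sinusitis NOS,4833,62681,7.7
2859,Anemia NOS,4632,62681,7.4
73300,Osteoporosis NOS,4529,62681,7.2
41401,Coronary atherosclerosis native vessel,4325,62681,6.9
53081,Esophageal reflux,4288,62681,6.8
7020,Actinic keratosis,4249,62681,6.8
73390,Bone & cartilage disease NOS,4113,62681,6.6
4659,Acute upper respiratory infection NOS,4112,62681,6.6
496,Chronic airway obstruct NEC,4041,62681,6.4
36616,Senile nuclear cataract,3914,62681,6.2
78609,Respiratory abnormality NEC,3605,62681,5.8
7840,Headache,3246,62681,5.2
41400,Coronary atherosclerosis unspec. vessel,3002,62681,4.8
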