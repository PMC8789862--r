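patient,sex,etiology,age_years,resected_area,defect_electrodes,followup_years,engel,asm_withdrawn
1,f,Ganglioglioma,1.5,R temporal,T4,1.5,IV,No
2,f,Low-grade glioma,2.5,L frontal,None,1.7,Ia,No
3,f,FCD 2b,2.8,R frontal,Fz,1.7,IV,No
4,f,MOGHE,3.6,L frontal,Fz;F3;C3,1.6,Ia,No
5,f,Sturge Weber syndrome,3.8,R temporo-occipital,O2;P4,4.2,Ia,No
6,f,FCD 2a,5.3,R frontal,C4,1.3,IV,No
7,m,FCD 1a,7.8,L temporo-parieto-occipital,T3;F7,4.8,Ia,No
8,m,Ganglioglioma,10.5,L temporal,T5,1.8,Ia,Yes
9,f,Angiocentric glioma,11.4,R parietal,Oz;Pz,1.0,Ia,Yes
10,m,FCD IIa,13.0,L parietal,T3;F7,1.0,IV,No
11,m,Cavernoma,13.1,L frontal,None,2.8,Ia,Yes
12,f,Ganglioglioma,16.0,L temporal,T3;F7,2.7,Ia,Yes
13,f,Cavernoma,16.3,L frontal,None,2.5,Ia,Yes
14,f,"FCD IIIb, ganglioglioma",16.5,R temporo-parietal,T6,2.0,Ia,Yes
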