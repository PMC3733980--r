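spot_id,accession,protein_name,0uM,5uM,50uM,500uM
1,P14625,Endoplasmin,1,0.27,0.33,0.20
2,P11142,Heat shock cognate 71 kDa protein,1,0.41,0.25,0.19
3,P11142,Heat shock cognate 71 kDa protein,1,3.13,2.58,2.79
4,P13639,Elongation factor 2,1,0.13,0.09,0.21
5,P08238,Heat shock protein HSP 90-beta,1,0.26,0.18,0.14
6,P07237,Protein disulfide-isomerase,1,0.07,0.22,0.09
7,P13489,Ribonuclease inhibitor,1,0.17,0.24,0.19
8,P22626,Heterogeneous nuclear ribonucleoproteins A2/B1,1,7.51,11.45,10.96
9,P63244,Guanine nucleotide-binding protein subunit beta-2-like 1,1,0.65,0.43,0.38
10,Q15056,Eukaryotic translation initiation factor 4H,1,0.32,0.15,0.27
11,P56537,Eukaryotic translation initiation factor 6,1,0.40,0.24,0.17
12,P09211,Glutathione S-transferase P,1,0.61,0.57,0.26
13,P30086,Phosphatidylethanolamine-binding protein 1,1,0.63,0.29,0.3
14,P62826,GTP-binding nuclear protein Ran,1,0.37,0.42,0.15
15,P60660,Myosin light polypeptide 6,1,0.34,0.49,0.08
16,P51854,Transketolase,1,4.17,3.30,1.85
17,Q6GMP2,Alpha-enolase,1,0.89,2.13,2.29
18,P31946,14-3-3 protein beta/alpha,1,0.76,0.50,0.55
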