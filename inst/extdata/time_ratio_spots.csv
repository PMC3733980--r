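spot_id,accession,protein_name,cluster,total_0h,total_24h,total_48h,phospho_0h,phospho_24h,phospho_48h
1,P49321,Nuclear autoantigenic sperm protein,e,1.00,0.37,1.35,1.00,0.09,0.05
2,P14625,Endoplasmin,f,1.00,1.17,0.26,,,
3,Q14697,Neutral alpha-glucosidase AB,e,1.00,0.41,0.89,,,
4,P11142,Heat shock cognate 71 kDa protein,d,1.00,0.62,0.45,1.00,0.13,0.08
5,P29401,Transketolase,f,1.00,3.23,0.77,,,
6,P31948,Stress-induced-phosphoprotein 1,d,1.00,0.61,0.28,1.00,1.17,0.19
7,P30101,Protein disulfide-isomerase A3,d,1.00,0.30,0.06,,,
8,P17987,T-complex protein 1 subunit alpha,d,1.00,0.39,0.21,,,
9,P31146,Coronin-1A,e,1.00,0.45,0.74,,,
10,P31943,Heterogeneous nuclear ribonucleoprotein H,d,1.00,0.88,0.49,,,
11,P07237,Protein disulfide-isomerase,e,1.00,0.37,0.84,,,
12,P13489,Ribonuclease inhibitor,d,1.00,0.91,0.23,,,
13,P27797,Calreticulin,f,1.00,3.58,0.95,,,
14,P06733,Alpha-enolase,f,1.00,2.37,0.82,1.00,0.24,0.07
15,Q86VC0,40S ribosomal protein SA,f,1.00,1.35,2.00,,,
16,P52597,Heterogeneous nuclear ribonucleoprotein F,e,1.00,0.31,0.73,,,
17,P52907,F-actin-capping protein subunit alpha-1,e,1.00,0.49,0.81,,,
18,O75821,Eukaryotic translation initiation factor 3 subunit I,e,1.00,0.29,0.72,1.00,0.73,0.29
19,P47755,F-actin-capping protein subunit alpha-2,e,1.00,0.43,0.87,1.00,0.20,0.03
20,P04083,Annexin A1,d,1.00,0.87,0.48,,,
21,P04406,Glyceraldehyde-3-phosphate dehydrogenase,e,1.00,0.39,1.25,,,
22,P04406,Glyceraldehyde-3-phosphate dehydrogenase,e,1.00,0.41,1.32,,,
23,P09651,Heterogeneous nuclear ribonucleoprotein A1,e,1.00,0.17,1.39,,,
24,P22626,Heterogeneous nuclear ribonucleoproteins A2/B1,e,1.00,0.06,0.33,,,
25,P52895,Aldo-keto reductase family 1 member C2,e,1.00,0.48,4.02,,,
26,Q9BYE2,Serine/threonine-protein kinase 13,d,1.00,0.11,0.07,,,
27,P08758,Annexin A5,d,1.00,0.43,0.36,,,
28,Q9Y275,14-3-3 protein epsilon,d,1.00,0.34,0.12,1.00,0.36,0.15
29,P31946,14-3-3 protein beta/alpha,d,1.00,0.39,0.22,1.00,0.31,0.74
30,P63104,14-3-3 protein zeta/delta,d,1.00,0.42,0.28,1.00,0.87,0.14
31,P56537,Eukaryotic translation initiation factor 6,e,1.00,0.39,0.47,1.00,0.76,0.41
32,P62258,Tumor necrosis factor ligand superfamily member 13B,f,1.00,2.13,0.29,1.00,0.33,0.17
33,Q6ZU15,Septin-14,e,1.00,0.04,0.78,,,
34,Q13162,Peroxiredoxin-4,e,1.00,0.20,0.53,,,
35,P18669,Phosphoglycerate mutase 1,e,1.00,0.08,2.59,,,
36,P63244,Guanine nucleotide-binding protein subunit beta-2-like 1,e,1.00,0.49,0.91,,,
37,P04792,Heat shock protein beta-1,d,1.00,0.43,0.28,,,
38,P30041,Peroxiredoxin-6,d,1.00,0.89,0.37,,,
39,P09211,Glutathione S-transferase P,d,1.00,0.77,0.42,1.00,0.26,0.04
40,P16949,Stathmin,e,1.00,0.35,0.46,,,
41,P15531,Nucleoside diphosphate kinase A,d,1.00,0.97,0.09,,,
42,P32119,Peroxiredoxin-2,e,1.00,0.37,0.49,,,
43,P60660,Myosin light polypeptide 6,d,1.00,0.88,0.23,,,
44,Q8N1F1,Putative uncharacterized protein NCRNA00188,f,1.00,1.15,0.50,,,
45,P05109,Protein S100-A8,e,1.00,0.29,0.73,,,
46,P62937,Peptidyl-prolyl cis-trans isomerase A,e,1.00,0.07,0.19,,,
47,Q969J3,Loss of heterozygosity 12 chromosomal region 1 protein,,,,,1.00,0.13,0.02
48,P63241,Eukaryotic translation initiation factor 5A-1,,,,,1.00,0.14,0.05
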