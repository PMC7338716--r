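patient_id,chrom,pos,ref,alt,gene,hgvs_c,hgvs_p,rsid,consequence,region,clinvar,inheritance,reference_note
2,17,68171000,G,T,KCNJ2,c.566G>T,p.Arg189Ile,rs199473381,missense,exonic,Likely pathogenic(1),AD,Congenital long QT syndrome
12,11,2593000,G,C,KCNQ1,c.914G>C,p.Trp305Ser,rs120074186,missense,exonic,Pathogenic(2);Likely pathogenic(1),AD,Long QT syndrome
29,5,147207000,A,G,SPINK1,c.101A>G,p.Asn34Ser,rs17107315,missense,exonic,Risk factor(2);Pathogenic(4);Uncertain significance(3),AR,Hereditary pancreatitis
29,7,117232000,T,G,CFTR,c.3154T>G,p.Phe1052Val,rs150212784,missense,exonic,Likely pathogenic(3);Pathogenic(2);Uncertain significance(4);Drug-response(1),AR,"Cystic fibrosis; Hereditary pancreatitis"
30,4,114270000,C,T,ANK2,c.11716C>T,p.Arg3906Trp,rs121912706,missense,exonic,Likely benign(4);Pathogenic(2);Uncertain significance(2),AD,"Cardiac arrhythmia; Long QT syndrome"
32,8,16012000,C,T,MSR1,c.877C>T,p.Arg293*,rs41341748,nonsense,exonic,Pathogenic(1);Uncertain significance(3);Benign(1),AD,"Malignant tumor of prostate; Hereditary cancer-predisposing syndrome"
32,1,182554000,G,T,RNASEL,c.793G>T,p.Glu265*,rs74315364,nonsense,exonic,Pathogenic(1);Likely benign(1);Uncertain significance(1),AD,Hereditary prostate cancer
32,21,35821000,G,A,KCNE1,c.253G>A,p.Asp85Asn,rs1805128,missense,exonic,Benign(5);Likely benign(5);risk factor(3);Pathogenic(1);Likely pathogenic(1);Uncertain significance(2),AD,Long QT syndrome
43,10,115348000,G,A,HABP2,c.1601G>A,p.Gly534Glu,rs7080536,missense,exonic,Risk factor(2);Likely benign(1);Benign(1),AD,"Thrombophilia, Thyroid cancer"
43,1,169519000,A,G,F5,c.A1601G,p.Q534R,rs6025,missense,exonic,Pathogenic(4);Risk factor(4);Benign(1),other,Thrombophilia
52,22,29121000,T,C,CHEK2,c.470T>C,p.Ile157Thr,rs17879961,missense,exonic,Likely pathogenic(8);Pathogenic(9);Risk factor(3);Uncertain significance(2),AD,Hereditary cancer risk
52,1,45797000,AGGA,A,MUTYH,c.1437_1439delGGA,p.Glu480del,rs587778541,inframe_indel,exonic,Pathogenic(14),AR,"MYH-associated polyposis; Hereditary cancer-predisposing syndrome"
56,11,46761000,G,A,F2,c.*97G>A,,rs1799963,utr3,utr,Pathogenic(4);Risk factor(4),other,"Prothrombin deficiency, congenital; Thrombophilia"
56,1,169519000,A,G,F5,c.A1601G,p.Q534R,rs6025,missense,exonic,Pathogenic(4);Risk factor(4);Benign(1),other,Thrombophilia
81,5,131931000,CA,C,RAD50,c.2801del,p.Asn934fs,rs748536322,frameshift,exonic,Pathogenic(1),AR,Hereditary cancer-predisposing syndrome
84,8,90983000,A,G,NBN,c.511A>G,p.Ile171Val,rs61754966,missense,exonic,Benign(3);Likely benign(1);Uncertain significance(11);Pathogenic(1);Risk factor(1),AR,Hereditary cancer-predisposing syndrome
91,5,112175000,T,A,APC,c.3920T>A,p.Ile1307Lys,rs1801155,missense,exonic,Likely benign(1);Likely pathogenic(3);Pathogenic(1);Uncertain significance(10);Risk factor(9),AD,Familial adenomatous polyposis
92,22,29121000,T,C,CHEK2,c.470T>C,p.Ile157Thr,rs17879961,missense,exonic,Likely pathogenic(8);Pathogenic(9);Risk factor(3);Uncertain significance(2),AD,Hereditary cancer risk
94,11,46761000,G,A,F2,c.*97G>A,,rs1799963,utr3,utr,Pathogenic(4);Risk factor(4),other,"Prothrombin deficiency, congenital; Thrombophilia"
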