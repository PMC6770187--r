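gene	overlap_cases	total_cases
40S ribosomal protein S8	177	755
60S ribosomal protein L17	136	527
Beta-arrestin-2	189	593
Dermcidin	141	579
Eukaryotic translation initiation factor 3 subunit K	248	954
Insulin-like growth factor 2 mRNA-binding protein 2	440	1729
Interferon-induced protein with tetratricopeptide repeats 3	192	965
Keratin 13	465	846
Keratin, type I cuticular Ha6	458	825
Keratin, type I cytoskeletal 17	471	862
Keratin, type II cytoskeletal 4	188	757
Large proline-rich protein BAG6	238	933
Low-density lipoprotein receptor-related protein 2	395	1525
Nuclear protein localization protein 4 homolog	425	1399
Proteasome inhibitor PI31 subunit	208	804
Protein disulfide-isomerase A4	274	1211
Regulator of G-protein signaling 10	201	854
Small nuclear ribonucleoprotein G	107	446
Splicing factor 3B subunit 1	249	958
UDP-glucose 6-dehydrogenase	143	481
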