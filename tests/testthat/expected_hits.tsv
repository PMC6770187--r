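protein	W	p_value	fold_change	stats_pass	rescue_pass	verdict	path
PROT0206	57.50525459	4.598886217e-06	3.69675332	TRUE	FALSE	hit	statistical
PROT0204	12.59002064	9.964174005e-05	5.491679152	TRUE	FALSE	hit	statistical
PROT0220	12.08889946	7.753938459e-05	NA	FALSE	TRUE	hit	rescue
PROT0208	10.11979019	0.0001782068007	4.3338399	TRUE	FALSE	hit	statistical
PROT0201	8.284229218	0.0003609186725	6.955616548	TRUE	FALSE	hit	statistical
PROT0207	7.551660419	0.0006273184828	4.103387109	TRUE	FALSE	hit	statistical
PROT0216	6.931752229	0.0004062059183	NA	FALSE	TRUE	hit	rescue
PROT0209	6.528603913	0.0007867811856	5.541928228	TRUE	FALSE	hit	statistical
PROT0211	6.13808837	0.0005820672069	NA	FALSE	TRUE	hit	rescue
PROT0217	6.020112981	0.0006163902071	NA	FALSE	TRUE	hit	rescue
PROT0210	5.185484421	0.002793157534	3.941922128	TRUE	FALSE	hit	statistical
PROT0215	4.964566095	0.00108660427	NA	FALSE	TRUE	hit	rescue
PROT0219	4.865211629	0.001152854148	NA	FALSE	TRUE	hit	rescue
PROT0203	4.829840002	0.002185823779	3.444359915	TRUE	FALSE	hit	statistical
PROT0218	4.815449447	0.001188053741	NA	FALSE	TRUE	hit	rescue
PROT0212	3.880546717	0.00222487848	NA	FALSE	TRUE	hit	rescue
PROT0202	3.648983643	0.004486100293	4.262024428	TRUE	FALSE	hit	statistical
PROT0205	3.638393593	0.007188658927	3.306637147	TRUE	FALSE	hit	statistical
PROT0213	3.582466934	0.002799996532	NA	FALSE	TRUE	hit	rescue
PROT0214	3.190169624	0.003897420605	NA	FALSE	TRUE	hit	rescue
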