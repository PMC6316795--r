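Metabolite	SuperPathway	SubPathway	HMDB	Loading
glycochenodeoxycholate sulfate	Lipid	Primary Bile Acid Metabolism		-9.12
stachydrine	Xenobiotics	Food Component/Plant	HMDB04827	-6.41
N-methylproline	Amino Acid	Urea cycle; Arginine and Proline Metabolism		-6.31
glycolithocholate sulfate	Lipid	Secondary Bile Acid Metabolism	HMDB02639	-4.87
methyl glucopyranoside (alpha + beta)	Xenobiotics	Food Component/Plant		-4.54
theobromine	Xenobiotics	Xanthine Metabolism	HMDB02825	-4.44
cysteine s-sulfate	Amino Acid	Methionine, Cysteine, SAM and Taurine Metabolism	HMDB00731	-4.23
4-vinylguaiacol sulfate	Xenobiotics	Food Component/Plant		-4.14
taurolithocholate 3-sulfate	Lipid	Secondary Bile Acid Metabolism	HMDB02580	-4.12
3-hydroxyhippurate	Xenobiotics	Benzoate Metabolism	HMDB06116	-3.72
2,3-dihydroxyisovalerate	Xenobiotics	Food Component/Plant	HMDB12141	-3.34
4-methylcatechol sulfate	Xenobiotics	Benzoate Metabolism		-3.33
vanillic alcohol sulfate	Amino Acid	Tyrosine Metabolism		-3.25
3-(3-hydroxyphenyl)propionate	Xenobiotics	Benzoate Metabolism	HMDB00375	-3.21
p-cresol-glucuronide	Amino Acid	Tyrosine Metabolism	HMDB11686	-3.2
CMP	Nucleotide	Pyrimidine Metabolism, Cytidine containing	HMDB00095	-3.16
indolepropionate	Amino Acid	Tryptophan Metabolism	HMDB02302	-3.11
beta-cryptoxanthin	Xenobiotics	Food Component/Plant	HMDB33844	-3.08
xylose	Carbohydrate	Pentose Metabolism	HMDB00098	-3.05
tauro-beta-muricholate	Lipid	Primary Bile Acid Metabolism	HMDB00932	-3.04
5-hydroxyindoleacetate	Amino Acid	Tryptophan Metabolism	HMDB00763	-2.93
gamma-glutamylglutamate	Peptide	Gamma-glutamyl Amino Acid	HMDB11737	-2.87
ferulic acid 4-sulfate	Xenobiotics	Food Component/Plant	HMDB29200	-2.8
cinnamoylglycine	Xenobiotics	Food Component/Plant	HMDB11621	-2.71
tryptophan betaine	Amino Acid	Tryptophan Metabolism	HMDB61115	-2.7
1,2,3-benzenetriol sulfate (2)	Xenobiotics	Chemical		-2.66
catechol sulfate	Xenobiotics	Benzoate Metabolism	HMDB59724	-2.65
quinate	Xenobiotics	Food Component/Plant	HMDB03072	-2.62
inosine 5'-monophosphate (IMP)	Nucleotide	Purine Metabolism, (Hypo)Xanthine/Inosine containing	HMDB00175	-2.59
gamma-glutamylvaline	Peptide	Gamma-glutamyl Amino Acid	HMDB11172	-2.58
ergothioneine	Xenobiotics	Food Component/Plant	HMDB03045	-2.49
ribitol	Carbohydrate	Pentose Metabolism	HMDB00508	-2.49
glycerophosphoinositol	Lipid	Phospholipid Metabolism		-2.49
umbelliferone sulfate	Xenobiotics	Food Component/Plant		-2.43
pyrraline	Xenobiotics	Food Component/Plant	HMDB33143	-2.4
4-acetylphenyl sulfate	Xenobiotics	Drug		-2.37
gamma-glutamylisoleucine	Peptide	Gamma-glutamyl Amino Acid	HMDB11170	-2.36
N-acetylproline	Amino Acid	Urea cycle; Arginine and Proline Metabolism		-2.34
3-methoxycatechol sulfate (1)	Xenobiotics	Benzoate Metabolism		-2.32
4-vinylphenol sulfate	Xenobiotics	Benzoate Metabolism	HMDB04072	-2.29
sphinganine	Lipid	Sphingolipid Metabolism	HMDB00269	-2.29
hydantoin-5-propionic acid	Amino Acid	Histidine Metabolism	HMDB01212	-2.23
trigonelline (N'-methylnicotinate)	Cofactors and Vitamins	Nicotinate and Nicotinamide Metabolism	HMDB00875	-2.19
O-methylcatechol sulfate	Xenobiotics	Benzoate Metabolism	HMDB60013	-2.18
4-allylphenol sulfate	Xenobiotics	Food Component/Plant		-2.16
2-aminophenol sulfate	Xenobiotics	Chemical	HMDB61116	-2.14
citrulline	Amino Acid	Urea cycle; Arginine and Proline Metabolism	HMDB00904	-2.13
uridine 3'-monophosphate (3'-UMP)	Nucleotide	Pyrimidine Metabolism, Uracil containing		-2.09
3-methyl catechol sulfate (1)	Xenobiotics	Benzoate Metabolism		-2.09
3-hydroxypyridine sulfate	Xenobiotics	Chemical		-2.06
isoursodeoxycholate	Lipid	Secondary Bile Acid Metabolism	HMDB00686	-2.05
propyl 4-hydroxybenzoate sulfate	Xenobiotics	Benzoate Metabolism		2.18
2'-O-methylcytidine	Nucleotide	Pyrimidine Metabolism, Cytidine containing		2.33
methyl-4-hydroxybenzoate sulfate	Xenobiotics	Benzoate Metabolism		2.37
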