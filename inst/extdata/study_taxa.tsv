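# Taxon metadata for the 66-sequence ascomycete nucSSU+nucLSU rRNA dataset:
# higher rank (class or outgroup phylum), species and GenBank accession of
# the SSU and LSU sequences, and ingroup/outgroup flag.  The taxon label is
# the SSU species name with underscores.
taxon	class	ssu_species	ssu_accession	lsu_species	lsu_accession	group
Chaetomium_globosum	Sordariomycetes	Chaetomium globosum	AY545725	Chaetomium globosum	AAFU01000611	ingroup
Diaporthe_sp	Sordariomycetes	Diaporthe sp.	AB245446	Diaporthe angelicae	AY196781	ingroup
Halosarpheia_retorquens	Sordariomycetes	Halosarpheia retorquens	AF050486	Halosarpheia japonica	HQ009884	ingroup
Hypocrea_rufa	Sordariomycetes	Hypocrea rufa	AY489694	Hypocrea jecorina	AF510497	ingroup
Meliola_niessleana	Sordariomycetes	Meliola niessleana	AF021794	Meliola variaseta	EF094840	ingroup
Microascus_cirrosus	Sordariomycetes	Microascus cirrosus	M89994	Microascus trigonosporus	DQ470958	ingroup
Neurospora_crassa	Sordariomycetes	Neurospora crassa	X04971	Neurospora crassa	FJ360521	ingroup
Sordaria_fimicola	Sordariomycetes	Sordaria fimicola	X69851	Sordaria fimicola	AY545728	ingroup
Xylaria_carpophila	Sordariomycetes	Xylaria carpophila	Z49785	Xylaria hypoxylon	AY544648	ingroup
Ascocoryne_solitaria	Leotiomycetes	Ascocoryne solitaria	DQ002904	Ascocoryne sarcoides	FJ176886	ingroup
Bulgaria_inquinans	Leotiomycetes	Bulgaria inquinans	AJ224362	Bulgaria inquinans	DQ470960	ingroup
Caespitotheca_forestalis	Leotiomycetes	Caespitotheca forestalis	AB193465	Caespitotheca forestalis	AB193467	ingroup
Coccomyces_dentatus	Leotiomycetes	Coccomyces dentatus	AY544701	Coccomyces strobi	DQ470975	ingroup
Erysiphe_mori	Leotiomycetes	Erysiphe mori	AB033484	Erysiphe pisi	CACM01000006	ingroup
Leotia_lubrica	Leotiomycetes	Leotia lubrica	AY544687	Leotia lubrica	AY544644	ingroup
Sclerotinia_sclerotiorum	Leotiomycetes	Sclerotinia sclerotiorum	AY187065	Sclerotinia sclerotiorum	DQ470965	ingroup
Thelebolus_ellipsoideus	Leotiomycetes	Thelebolus ellipsoideus	DQ067574	Thelebolus ellipsoideus	FJ176895	ingroup
Geoglossum_nigritum	Geoglossomycetes	Geoglossum nigritum	AF113716	Geoglossum nigritum	AY544650	ingroup
Sarcoleotia_globosa	Geoglossomycetes	Sarcoleotia globosa	AY789298	Sarcoleotia globosa	AY789428	ingroup
Trichoglossum_hirsutum	Geoglossomycetes	Trichoglossum hirsutum	AY544697	Trichoglossum hirsutum	AY544653	ingroup
Aspergillus_penicillioides	Eurotiomycetes	Aspergillus penicillioides	AB002060	Aspergillus protuberus	FJ176897	ingroup
Capronia_coronata	Eurotiomycetes	Capronia coronata	AJ232939	Capronia mansonii	AY004338	ingroup
Catapyrenium_lachneum	Eurotiomycetes	Catapyrenium lachneum	AF412410	Catapyrenium cinereum	EF643747	ingroup
Elaphomyces_maculatus	Eurotiomycetes	Elaphomyces maculatus	U45440	Elaphomyces guangdongensis	HM357248	ingroup
Eupenicillium_crustaceum	Eurotiomycetes	Eupenicillium crustaceum	D88324	Eupenicillium ochrosalmoneum	EF626957	ingroup
Eurotium_rubrum	Eurotiomycetes	Eurotium rubrum	U00970	Eurotium sp.	FR848827	ingroup
Monascus_purpureus	Eurotiomycetes	Monascus purpureus	DQ782881	Monascus purpureus	DQ782908	ingroup
Onygena_equina	Eurotiomycetes	Onygena equina	U45442	Onygena corvina	FJ358287	ingroup
Trichophyton_rubrum	Eurotiomycetes	Trichophyton rubrum	X58570	Trichophyton equinum	ABWI01001612	ingroup
Cladonia_rangiferina	Lecanoromycetes	Cladonia rangiferina	AF184753	Cladonia stipitata	DQ973026	ingroup
Lecanora_dispersa	Lecanoromycetes	Lecanora dispersa	L37734	Lecanora contractula	DQ986746	ingroup
Parmelia_saxatilis	Lecanoromycetes	Parmelia saxatilis	AF117985	Parmelia saxatilis	AY300849	ingroup
Physcia_aipolia	Lecanoromycetes	Physcia aipolia	AF241542	Physcia aipolia	DQ782904	ingroup
Usnea_florida	Lecanoromycetes	Usnea florida	AF117988	Usnea strigosa	DQ973033	ingroup
Botryosphaeria_ribis	Dothideomycetes	Botryosphaeria ribis	U42477	Botryosphaeria stevensii	DQ678064	ingroup
Cochliobolus_sativus	Dothideomycetes	Cochliobolus sativus	U42479	Cochliobolus sativus	DQ678045	ingroup
Dothidea_sambuci	Dothideomycetes	Dothidea sambuci	AY544722	Dothidea insculpta	DQ247802	ingroup
Leptosphaeria_maculans	Dothideomycetes	Leptosphaeria maculans	DQ470993	Leptosphaeria maculans	DQ470946	ingroup
Mycosphaerella_mycopappi	Dothideomycetes	Mycosphaerella mycopappi	U43463	Mycosphaerella pneumatophorae	FJ176856	ingroup
Myriangium_duriaei	Dothideomycetes	Myriangium duriaei	AY016347	Myriangium duriaei	DQ678059	ingroup
Pleospora_herbarum	Dothideomycetes	Pleospora herbarum	U05201	Pleospora sp.	EF177848	ingroup
Rhytidhysteron_rufulum	Dothideomycetes	Rhytidhysteron rufulum	AF201452	Rhytidhysteron rufulum	GU397353	ingroup
Acervus_epispartius	Pezizomycetes	Acervus epispartius	DQ787814	Acervus epispartius	DQ220305	ingroup
Chorioactis_geaster	Pezizomycetes	Chorioactis geaster	AF104340	Chorioactis geaster	AY307945	ingroup
Galiella_rufa	Pezizomycetes	Galiella rufa	AF004948	Galiella rufa	FJ176869	ingroup
Morchella_esculenta	Pezizomycetes	Morchella esculenta	U42642	Morchella cf. elata	AY544665	ingroup
Otidea_leporina	Pezizomycetes	Otidea leporina	DQ248955	Otidea leporina	DQ220386	ingroup
Phillipsia_domingensis	Pezizomycetes	Phillipsia domingensis	AF006315	Phillipsia olivacea	AY945843	ingroup
Pseudopithyella_minuscula	Pezizomycetes	Pseudopithyella minuscula	AF006317	Pseudopithyella minuscula	AY544658	ingroup
Pyronema_domesticum	Pezizomycetes	Pyronema domesticum	U53385	Pyronema domesticum	DQ247805	ingroup
Sarcoscypha_coccinea	Pezizomycetes	Sarcoscypha coccinea	AY544691	Sarcoscypha coccinea	FJ176859	ingroup
Scutellinia_korfiana	Pezizomycetes	Scutellinia korfiana	DQ787829	Scutellinia scutellata	DQ247806	ingroup
Tuber_gibbosum	Pezizomycetes	Tuber gibbosum	U42663	Tuber gibbosum	FJ176877	ingroup
Wolfina_aurantiopsis	Pezizomycetes	Wolfina aurantiopsis	AF104664	Wolfina aurantiopsis	AY945859	ingroup
Orbilia_auricolor	Orbiliomycetes	Orbilia auricolor	DQ471001	Orbilia auricolor	DQ470953	ingroup
Orbilia_delicatula	Orbiliomycetes	Orbilia delicatula	U72603	Orbilia delicatula	AY261178	ingroup
Neolecta_vitellina	Neolectomycetes	Neolecta vitellina	DQ471037	Neolecta vitellina	DQ470985	ingroup
Neolecta_irregularis	Neolectomycetes	Neolecta irregularis	DQ842040	Neolecta irregularis	DQ470986	ingroup
Candida_glabrata	Saccharomycetes	Candida glabrata	AY218893	Candida albicans	DM167147	ingroup
Saccharomyces_cerevisiae	Saccharomycetes	Saccharomyces cerevisiae	U53879	Saccharomyces cerevisiae	U53879	ingroup
Protomyces_inouyei	Taphrinomycetes	Protomyces inouyei	D11377	Protomyces inouyei	AY548294	ingroup
Taphrina_deformans	Taphrinomycetes	Taphrina deformans	U00971	Taphrina deformans	DQ470973	ingroup
Schizosaccharomyces_pombe	Schizosaccharomycetes	Schizosaccharomyces pombe	X54866	Schizosaccharomyces japonicus	AATM01000140	ingroup
Chytridium_polysiphoniae	Chytridiomycota	Chytridium polysiphoniae	AY032608	Chytridium sp.	DQ273831	outgroup
Mucor_racemosus	Zygomycota	Mucor racemosus	AJ271061	Mucor racemosus	M26190	outgroup
Rhizopus_oryzae	Zygomycota	Rhizopus oryzae	AB250174	Rhizopus oryzae	AACW02000152	outgroup
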