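# Morphological character codings for the 66-taxon dataset, encoded at
# class level from the character definitions and clade descriptions.
# ascus (dehiscence mechanism), 6 states: schizo_saccharomyces (wall
#   deliquescence, base/top undifferentiated), taphrina_neolecta (apical
#   slit), orbilia (tearing of flattened apex), operculate (apical lid),
#   bitunicate (two-layered extensible wall), inoperculate (apical pore).
# ascoma (fruitbody) shape, 3 states: absent, exposed_hymenium,
#   ostiolar_sealed.
# Coding notes: Eurotiomycetes asci are deliquescent (schizo_saccharomyces
#   state) within a sealed fruitbody.  Leotiomycetes are apothecial except
#   Caespitotheca and Erysiphe (ostiolar/sealed).  Dothideomycetes are
#   coded ostiolar_sealed throughout although part of the class is
#   apothecial; the source descriptions do not name which sampled taxa,
#   so the class-level state is used (AMBIGUOUS, not a per-taxon datum).
# Outgroup taxa (Chytridiomycota, Zygomycota) form no asci: ascus is
#   missing (-), ascoma is absent.
taxon	class	ascus	ascoma
Chaetomium_globosum	Sordariomycetes	inoperculate	ostiolar_sealed
Diaporthe_sp	Sordariomycetes	inoperculate	ostiolar_sealed
Halosarpheia_retorquens	Sordariomycetes	inoperculate	ostiolar_sealed
Hypocrea_rufa	Sordariomycetes	inoperculate	ostiolar_sealed
Meliola_niessleana	Sordariomycetes	inoperculate	ostiolar_sealed
Microascus_cirrosus	Sordariomycetes	inoperculate	ostiolar_sealed
Neurospora_crassa	Sordariomycetes	inoperculate	ostiolar_sealed
Sordaria_fimicola	Sordariomycetes	inoperculate	ostiolar_sealed
Xylaria_carpophila	Sordariomycetes	inoperculate	ostiolar_sealed
Ascocoryne_solitaria	Leotiomycetes	inoperculate	exposed_hymenium
Bulgaria_inquinans	Leotiomycetes	inoperculate	exposed_hymenium
Caespitotheca_forestalis	Leotiomycetes	inoperculate	ostiolar_sealed
Coccomyces_dentatus	Leotiomycetes	inoperculate	exposed_hymenium
Erysiphe_mori	Leotiomycetes	inoperculate	ostiolar_sealed
Leotia_lubrica	Leotiomycetes	inoperculate	exposed_hymenium
Sclerotinia_sclerotiorum	Leotiomycetes	inoperculate	exposed_hymenium
Thelebolus_ellipsoideus	Leotiomycetes	inoperculate	exposed_hymenium
Geoglossum_nigritum	Geoglossomycetes	inoperculate	exposed_hymenium
Sarcoleotia_globosa	Geoglossomycetes	inoperculate	exposed_hymenium
Trichoglossum_hirsutum	Geoglossomycetes	inoperculate	exposed_hymenium
Aspergillus_penicillioides	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Capronia_coronata	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Catapyrenium_lachneum	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Elaphomyces_maculatus	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Eupenicillium_crustaceum	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Eurotium_rubrum	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Monascus_purpureus	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Onygena_equina	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Trichophyton_rubrum	Eurotiomycetes	schizo_saccharomyces	ostiolar_sealed
Cladonia_rangiferina	Lecanoromycetes	bitunicate	exposed_hymenium
Lecanora_dispersa	Lecanoromycetes	bitunicate	exposed_hymenium
Parmelia_saxatilis	Lecanoromycetes	bitunicate	exposed_hymenium
Physcia_aipolia	Lecanoromycetes	bitunicate	exposed_hymenium
Usnea_florida	Lecanoromycetes	bitunicate	exposed_hymenium
Botryosphaeria_ribis	Dothideomycetes	bitunicate	ostiolar_sealed
Cochliobolus_sativus	Dothideomycetes	bitunicate	ostiolar_sealed
Dothidea_sambuci	Dothideomycetes	bitunicate	ostiolar_sealed
Leptosphaeria_maculans	Dothideomycetes	bitunicate	ostiolar_sealed
Mycosphaerella_mycopappi	Dothideomycetes	bitunicate	ostiolar_sealed
Myriangium_duriaei	Dothideomycetes	bitunicate	ostiolar_sealed
Pleospora_herbarum	Dothideomycetes	bitunicate	ostiolar_sealed
Rhytidhysteron_rufulum	Dothideomycetes	bitunicate	ostiolar_sealed
Acervus_epispartius	Pezizomycetes	operculate	exposed_hymenium
Chorioactis_geaster	Pezizomycetes	operculate	exposed_hymenium
Galiella_rufa	Pezizomycetes	operculate	exposed_hymenium
Morchella_esculenta	Pezizomycetes	operculate	exposed_hymenium
Otidea_leporina	Pezizomycetes	operculate	exposed_hymenium
Phillipsia_domingensis	Pezizomycetes	operculate	exposed_hymenium
Pseudopithyella_minuscula	Pezizomycetes	operculate	exposed_hymenium
Pyronema_domesticum	Pezizomycetes	operculate	exposed_hymenium
Sarcoscypha_coccinea	Pezizomycetes	operculate	exposed_hymenium
Scutellinia_korfiana	Pezizomycetes	operculate	exposed_hymenium
Tuber_gibbosum	Pezizomycetes	operculate	exposed_hymenium
Wolfina_aurantiopsis	Pezizomycetes	operculate	exposed_hymenium
Orbilia_auricolor	Orbiliomycetes	orbilia	exposed_hymenium
Orbilia_delicatula	Orbiliomycetes	orbilia	exposed_hymenium
Neolecta_vitellina	Neolectomycetes	taphrina_neolecta	exposed_hymenium
Neolecta_irregularis	Neolectomycetes	taphrina_neolecta	exposed_hymenium
Candida_glabrata	Saccharomycetes	schizo_saccharomyces	absent
Saccharomyces_cerevisiae	Saccharomycetes	schizo_saccharomyces	absent
Protomyces_inouyei	Taphrinomycetes	taphrina_neolecta	absent
Taphrina_deformans	Taphrinomycetes	taphrina_neolecta	absent
Schizosaccharomyces_pombe	Schizosaccharomycetes	schizo_saccharomyces	absent
Chytridium_polysiphoniae	Chytridiomycota	-	absent
Mucor_racemosus	Zygomycota	-	absent
Rhizopus_oryzae	Zygomycota	-	absent
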