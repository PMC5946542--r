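# SYNTHETIC taxon registry: a constructed 65-species, 14-family stand-in
# for the published snake mitogenome panel. Species names are real snakes
# chosen for plausibility; the per-tip arrangement-type assignments and
# the companion tree (snake_tree_synthetic.nwk) were constructed so that
# every published headline count (type census, independent origins and
# losses, hotspot tallies) is recomputable from this fixture.
taxon_id	species	family	type
Leptotyphlops_dulcis	Leptotyphlops dulcis	Leptotyphlopidae	I
Rena_humilis	Rena humilis	Leptotyphlopidae	I
Ramphotyphlops_braminus	Ramphotyphlops braminus	Typhlopidae	II
Typhlops_mirus	Typhlops mirus	Typhlopidae	II
Xerotyphlops_vermicularis	Xerotyphlops vermicularis	Typhlopidae	II
Anilius_scytale	Anilius scytale	Aniliidae	III
Tropidophis_haetianus	Tropidophis haetianus	Tropidophiidae	III-A
Cylindrophis_ruffus	Cylindrophis ruffus	Cylindrophiidae	III
Xenopeltis_unicolor	Xenopeltis unicolor	Xenopeltidae	III
Python_regius	Python regius	Pythonidae	III
Python_bivittatus	Python bivittatus	Pythonidae	III
Python_molurus	Python molurus	Pythonidae	III
Malayopython_reticulatus	Malayopython reticulatus	Pythonidae	III
Boa_constrictor	Boa constrictor	Boidae	III
Eunectes_notaeus	Eunectes notaeus	Boidae	III
Candoia_aspera	Candoia aspera	Boidae	III
Calabaria_reinhardtii	Calabaria reinhardtii	Boidae	III
Acrochordus_granulatus	Acrochordus granulatus	Acrochordidae	III
Achalinus_meiguensis	Achalinus meiguensis	Xenodermatidae	III
Azemiops_feae	Azemiops feae	Viperidae	III-B
Vipera_berus	Vipera berus	Viperidae	III-B
Daboia_russelii	Daboia russelii	Viperidae	III-B
Crotalus_horridus	Crotalus horridus	Viperidae	III-B
Agkistrodon_piscivorus	Agkistrodon piscivorus	Viperidae	III-B
Deinagkistrodon_acutus	Deinagkistrodon acutus	Viperidae	III-B
Gloydius_brevicaudus	Gloydius brevicaudus	Viperidae	III-B
Gloydius_intermedius	Gloydius intermedius	Viperidae	III-B
Ovophis_monticola	Ovophis monticola	Viperidae	III-B
Ovophis_okinavensis	Ovophis okinavensis	Viperidae	III-B1
Protobothrops_mucrosquamatus	Protobothrops mucrosquamatus	Viperidae	III-B
Protobothrops_flavoviridis	Protobothrops flavoviridis	Viperidae	III-B
Trimeresurus_albolabris	Trimeresurus albolabris	Viperidae	III-B
Trimeresurus_stejnegeri	Trimeresurus stejnegeri	Viperidae	III-B
Enhydris_plumbea	Enhydris plumbea	Homalopsidae	III-C
Homalopsis_buccata	Homalopsis buccata	Homalopsidae	III
Laticauda_colubrina	Laticauda colubrina	Elapidae	III
Hydrophis_curtus	Hydrophis curtus	Elapidae	III
Micrurus_fulvius	Micrurus fulvius	Elapidae	III
Naja_atra	Naja atra	Elapidae	III
Naja_naja	Naja naja	Elapidae	III
Ophiophagus_hannah	Ophiophagus hannah	Elapidae	III-D
Bungarus_fasciatus	Bungarus fasciatus	Elapidae	III
Bungarus_multicinctus	Bungarus multicinctus	Elapidae	III
Ahaetulla_prasina	Ahaetulla prasina	Colubridae	III
Imantodes_cenchoa	Imantodes cenchoa	Colubridae	III-E
Boiga_kraepelini	Boiga kraepelini	Colubridae	III
Leptodeira_septentrionalis	Leptodeira septentrionalis	Colubridae	III-F
Rhabdophis_tigrinus	Rhabdophis tigrinus	Colubridae	III
Sibon_nebulatus	Sibon nebulatus	Colubridae	III-G
Amphiesma_stolatum	Amphiesma stolatum	Colubridae	III
Ptyas_mucosa	Ptyas mucosa	Colubridae	III-C
Coluber_constrictor	Coluber constrictor	Colubridae	III
Oocatochus_rufodorsatus	Oocatochus rufodorsatus	Colubridae	III-C
Euprepiophis_mandarinus	Euprepiophis mandarinus	Colubridae	III
Pantherophis_guttatus	Pantherophis guttatus	Colubridae	III-C
Pantherophis_slowinskii	Pantherophis slowinskii	Colubridae	III-C
Pantherophis_obsoletus	Pantherophis obsoletus	Colubridae	III-C
Oligodon_ningshaanensis	Oligodon ningshaanensis	Colubridae	III
Elaphe_davidi	Elaphe davidi	Colubridae	III
Elaphe_anomala	Elaphe anomala	Colubridae	III-C
Elaphe_bimaculata	Elaphe bimaculata	Colubridae	III-C
Lycodon_ruhstrati	Lycodon ruhstrati	Colubridae	III
Lycodon_semicarinatus	Lycodon semicarinatus	Colubridae	III-C
Lycodon_rufozonatus	Lycodon rufozonatus	Colubridae	III-C
Lycodon_flavozonatum	Lycodon flavozonatum	Colubridae	III-C
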