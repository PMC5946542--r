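((Leptotyphlops_dulcis,Rena_humilis),((Ramphotyphlops_braminus,(Typhlops_mirus,Xerotyphlops_vermicularis)),((Anilius_scytale,Tropidophis_haetianus),(((Cylindrophis_ruffus,Xenopeltis_unicolor,(Python_regius,(Python_bivittatus,(Python_molurus,Malayopython_reticulatus)))),(Boa_constrictor,(Eunectes_notaeus,(Candoia_aspera,Calabaria_reinhardtii)))),(Acrochordus_granulatus,(Achalinus_meiguensis,((Azemiops_feae,((Vipera_berus,Daboia_russelii),((Crotalus_horridus,Agkistrodon_piscivorus),((Deinagkistrodon_acutus,(Gloydius_brevicaudus,Gloydius_intermedius)),((Ovophis_monticola,Ovophis_okinavensis),(Protobothrops_mucrosquamatus,(Protobothrops_flavoviridis,(Trimeresurus_albolabris,Trimeresurus_stejnegeri)))))))),((Enhydris_plumbea,Homalopsis_buccata),((Laticauda_colubrina,((Hydrophis_curtus,Micrurus_fulvius),((Naja_atra,Naja_naja),(Ophiophagus_hannah,(Bungarus_fasciatus,Bungarus_multicinctus))))),(Ahaetulla_prasina,((Imantodes_cenchoa,Boiga_kraepelini),((Leptodeira_septentrionalis,Rhabdophis_tigrinus),((Sibon_nebulatus,Amphiesma_stolatum),((Ptyas_mucosa,Coluber_constrictor),((Oocatochus_rufodorsatus,Euprepiophis_mandarinus),(((Pantherophis_guttatus,(Pantherophis_slowinskii,Pantherophis_obsoletus)),Oligodon_ningshaanensis),((Elaphe_davidi,(Elaphe_anomala,Elaphe_bimaculata)),(Lycodon_ruhstrati,(Lycodon_semicarinatus,(Lycodon_rufozonatus,Lycodon_flavozonatum))))))))))))))))))));
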