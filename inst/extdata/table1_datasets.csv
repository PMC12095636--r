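site,region,species,stage,zone,zone_name,treatment,area_ha,releases_per_week_ha,n_traps,n_sessions,total_count
1,La Reunion,aedes_spp,egg,treated,Chemin Damour,Boosted SIT,10,353,7,63,1917
1,La Reunion,aedes_spp,egg,control,Langevin,Control,50,NA,5,45,2014
1,La Reunion,aegypti,adult,treated,Chemin Damour,Boosted SIT,10,353,7,146,425
1,La Reunion,aegypti,adult,control,Langevin,Control,50,NA,5,82,856
1,La Reunion,albopictus,adult,treated,Chemin Damour,Boosted SIT,10,353,7,146,333
1,La Reunion,albopictus,adult,control,Langevin,Control,50,NA,5,82,256
2,Valencia,albopictus,egg,treated,La Vilavella,Boosted SIT,35,2712,35,630,16514
2,Valencia,albopictus,egg,control,Betxi,Control,200,NA,20,357,17946
2,Valencia,albopictus,adult,treated,La Vilavella,Boosted SIT,35,2712,35,630,1466
2,Valencia,albopictus,adult,control,Betxi,Control,200,NA,20,357,2837
3,Valencia,albopictus,egg,treated,Polinya de Xuquer East,Boosted SIT,23,2620,23,392,8193
3,Valencia,albopictus,egg,control,Albalat de la Ribera,Control,590,NA,59,991,43319
3,Valencia,albopictus,adult,treated,Polinya de Xuquer East,Boosted SIT,23,2620,23,392,773
3,Valencia,albopictus,adult,control,Albalat de la Ribera,Control,590,NA,59,991,7070
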