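scientific_name,common_name,species,n,forage_substrate,diet,nest_substrate
Empidonax alnorum,Alder Flycatcher,ALFL,15,A,I,Treed/shrubby swamp
Setophaga ruticilla,American Redstart,AMRE,14,LCS,I,Deciduous Woodland
Cardellina canadensis,Canada Warbler,CAWA,14,LCS,I,Deciduous Woodland
Spizella pallida,Clay-coloured Sparrow,CCSP,15,G,O,Coniferous Woodland
Bombycilla cedrorum,Cedar Waxwing,CEDW,12,A,I,Open Woodland
Spizella passerina,Chipping Sparrow,CHSP,15,G,O,Open Woodland
Geothlypis trichas,Common Yellowthroat,COYE,9,LCS,I,Marsh
Empidonax minimus,Least Flycatcher,LEFL,15,A,I,Deciduous Woodland
Melospiza lincolnii,Lincoln's Sparrow,LISP,12,G,O,Bogs
Setophaga magnolia,Magnolia Warbler,MAWA,11,LCS,I,Mixed Woodland
Geothlypis philadelphia,Mourning Warbler,MOWA,13,G,I,Open Woodland
Setophaga coronata,Yellow-rumped Warbler,YRWA,13,LCS,I,Coniferous Woodland
Seiurus aurocapilla,Ovenbird,OVEN,11,G,I,Deciduous Woodland
Vireo olivaceus,Red-eyed Vireo,REVI,15,UC,I,Deciduous Woodland
Passerculus sandwichensis,Savannah Sparrow,SAVS,14,G,O,Agricultural
Melospiza melodia,Song Sparrow,SOSP,12,LCS,O,Early Successional
Catharus ustulatus,Swainson's Thrush,SWTH,14,G,O,Mixed Woodland
Oreothlypis peregrina,Tennessee Warbler,TEWA,14,UC,I,Bogs
Tachycineta bicolor,Tree Swallow,TRES,15,A,I,Treed/shrubby swamp
Zonotrichia albicollis,White-throated Sparrow,WTSP,13,G,O,Early Successional
Setophaga petechia,Yellow Warbler,YEWA,13,LCS,I,Early Successional
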