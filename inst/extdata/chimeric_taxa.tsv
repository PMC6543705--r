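chimera	members
Aplysia_Biomphalaria	Aplysia_californica,Biomphalaria_glabrata
Brachionus	Brachionus_plicatilis,Brachionus_manjavacas
Chiton_Chaetopleura	Chiton_olivaceus,Chaetopleura_apiculata
Clonorchis_Opisthorchis	Clonorchis_sinensis,Opisthorchis_viverrini
Dugesia	Dugesia_japonica,Dugesia_ryukyuensis
Echinococcus	Echinococcus_granulosus,Echinococcus_multilocularis
Echinorhynchus	Echinorhynchus_gadi,Echinorhynchus_truttae
Euprymna_Idiosepius	Euprymna_scolopes,Idiosepius_paradoxus
Lepadella_Lecane	Lepadella_patella,Lecane_inermis
Pedicellina	Pedicellina_sp,Pedicellina_cernua
Protodrilloides	Protodrilloides_symbioticus,Protodrilloides_chaetifer
Schistosoma	Schistosoma_mansoni,Schistosoma_japonicum
Spiochaetopterus_Chaetopterus	Spiochaetopterus_sp,Chaetopterus_variopedatus
Stenostomum	Stenostomum_leucops,Stenostomum_sthenum
Symbion	Symbion_pandora,Symbion_americanus
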