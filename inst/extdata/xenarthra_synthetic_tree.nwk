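((Dasypus_novemcinctus:45,(Chlamyphorus_truncatus:40,(Tolypeutes_matacus:33,Priodontes_maximus:33):7):5):20,(((Bradypus_tridactylus:8,Bradypus_variegatus:8):22,Choloepus_didactylus:30):28,(Cyclopes_didactylus:38,(Tamandua_mexicana:13,Myrmecophaga_tridactyla:13):25):20):7);
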