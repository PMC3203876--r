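(((Isolona_capuronii:5.0,(Isolona_ghesquierei:3.0,Isolona_perrierii:3.0):2.0):4.0,((Isolona_congolana:6.0,Isolona_hexaloba:6.0):2.0,((Isolona_pleurocarpa:4.5,Isolona_zenkeri:4.5):2.5,(Isolona_cauliflora:6.5,((Isolona_campanulata:2.8,Isolona_cooperi:2.8):2.2,((Isolona_dewevrei:2.5,Isolona_thonneri:2.5):1.5,(Isolona_heinsenii:2.6,Isolona_linearis:2.6):1.4):1.0):1.5):0.5):1.0):1.0):5.9,(((Monodora_crispata:3.8,Monodora_tenuifolia:3.8):2.2,(Monodora_angolensis:4.5,(Monodora_laurentii:2.4,Monodora_myristica:2.4,Monodora_undulata:2.4):2.1):1.5):4.0,(Monodora_grandidieri:5.0,(Monodora_minor:4.0,((Monodora_carolinae:2.6,Monodora_stenopetala:2.6):0.9,(Monodora_globiflora:2.2,(Monodora_hastipetala:1.5,Monodora_junodii:1.5):0.7):1.3):0.5):1.0):5.0):4.9);
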