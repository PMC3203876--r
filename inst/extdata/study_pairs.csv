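species_a,species_b,genus,mrca_age_ma,age_ci,overlap_pct,smaller_range
Isolona_pleurocarpa,Isolona_zenkeri,Isolona,4.5,1.4-7.9,19.6,Isolona_pleurocarpa
Isolona_dewevrei,Isolona_thonneri,Isolona,2.5,0.4-4.8,8.9,Isolona_dewevrei
Isolona_heinsenii,Isolona_linearis,Isolona,2.6,0.7-4.8,32,Isolona_linearis
Isolona_campanulata,Isolona_cooperi,Isolona,2.8,0.9-5.2,16,Isolona_cooperi
Isolona_congolana,Isolona_hexaloba,Isolona,6,2.7-9.8,12.6,Isolona_congolana
Monodora_carolinae,Monodora_stenopetala,Monodora,2.6,0.9-4.4,0,no overlap
Monodora_hastipetala,Monodora_junodii,Monodora,1.5,0.2-3.2,89.3,Monodora_hastipetala
Monodora_laurentii,Monodora_myristica,Monodora,2.4,0.6-4.8,14.3,Monodora_laurentii
Monodora_myristica,Monodora_undulata,Monodora,1.6,NE,35.7,Monodora_undulata
Monodora_crispata,Monodora_tenuifolia,Monodora,3.8,NE,43,Monodora_crispata
Monodora_laurentii,Monodora_undulata,Monodora,2.4,0.6-4.8,0,no overlap
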