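species,group,endfreq_lo_khz,endfreq_hi_khz,song_peak_freq_khz,source_level_db_pespl_1m,flight_speed_m_s,provenance
Nyctalus noctula,Nyctaloid,15,21.5,15,84.22,6,speed-literature; acoustics-calibrated
Nyctalus leisleri,Nyctaloid,23,28.5,16.5,80.93,5.5,calibrated
Vespertilio murinus,Nyctaloid,23,28.5,14,106.76,5,calibrated
Plecotus spp.,Nyctaloid,23,28.5,26.4,83.44,2.5,speed-literature; acoustics-calibrated
Pipistrellus nathusii,Pipistrelloid,31,41.5,17.5,97.23,4.5,calibrated
Pipistrellus pipistrellus,Pipistrelloid,43,50.5,20,80.82,3.5,calibrated
Pipistrellus pygmaeus,Pipistrelloid,52,58,21.5,78.7,3,calibrated
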