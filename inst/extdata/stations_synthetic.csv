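# Synthetic four-station geometry (not the field coordinates, which were
# never published): co-located seismo-acoustic stations ringing a central
# source region, aperture < 360 m.
id,x_m,y_m,modality
ETA,155,10,both
NTA,-10,150,both
STA,20,-145,both
WTA,-150,-20,both
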