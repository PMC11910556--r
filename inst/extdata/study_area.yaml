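# Study area: 18 Sentinel-2 MGRS granules (UTM/WGS84, 109.8 km side)
# covering the Caribbean coasts of Mexico, Belize, Guatemala and Honduras.
tile_ids:
  - T16QDJ
  - T16QEJ
  - T16QDH
  - T16QEH
  - T16QDG
  - T16QEG
  - T16QDF
  - T16QEF
  - T16QCF
  - T16QCE
  - T16QDE
  - T16QEE
  - T16QCD
  - T16QDD
  - T16QED
  - T16PCC
  - T16PDC
  - T16PEC
granule_side_km: 109.8
crs: UTM/WGS84
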