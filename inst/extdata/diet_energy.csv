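diet_id,me_intake_kj_kg075,thp_kj_kg075,fhp_kj_kg075,rep_kj_kg075,rel_kj_kg075,re_kj_kg075,rq_fed,rq_fasted,de_mj_kg_dm,me_mj_kg_dm,ne_mj_kg_dm
basal,540,438,348,73,39,111,0.99,0.81,15.62,14.37,12.23
BL-1,528,445,357,72,-35,37,0.93,0.76,15.53,14.35,11.98
BL-2,519,450,368,55,-25,30,0.93,0.77,14.50,13.56,11.42
BL-3,530,470,369,65,-33,32,0.93,0.76,14.84,13.96,11.84
BL-4,523,476,349,72,-30,42,1.00,0.83,15.88,14.69,12.16
BL-5,512,463,356,73,-44,29,1.00,0.83,15.13,13.78,11.50
BL-6,509,464,361,79,-11,68,0.97,0.80,15.00,13.85,11.65
BL-7,518,408,356,81,57,138,0.98,0.78,15.32,14.16,12.75
BL-8,507,423,362,76,35,111,0.96,0.78,15.01,13.71,12.24
BL-9,524,415,361,73,37,109,1.00,0.81,15.00,14.10,12.65
BL-10,531,425,380,72,56,128,0.99,0.81,15.18,14.23,13.02
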