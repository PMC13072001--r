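diet_id,ge,cp,ee,starch,ndf,adf,ash
basal,15.99,13.74,3.24,45.85,9.50,3.52,3.88
BL-1,15.95,14.10,2.87,42.98,12.60,4.03,3.81
BL-2,15.99,14.06,2.90,47.50,13.33,3.96,3.95
BL-3,15.91,14.78,2.70,45.38,12.74,3.64,4.22
BL-4,16.55,14.20,2.59,47.27,13.14,3.94,4.13
BL-5,15.84,13.83,2.65,47.09,13.92,4.52,3.77
BL-6,16.13,14.35,2.80,45.81,12.03,3.66,3.88
BL-7,16.08,14.83,2.87,45.52,11.15,3.25,3.99
BL-8,15.85,14.34,3.00,47.33,13.50,3.92,4.00
BL-9,15.89,14.26,2.77,45.67,13.11,3.80,4.13
BL-10,15.80,13.99,2.36,48.79,12.83,3.85,3.28
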