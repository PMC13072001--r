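diet_id,ingredient,inclusion_pct
basal,Corn,81.43
basal,Soybean meal,15.62
basal,Dicalcium phosphate,1.05
basal,Limestone,1.00
basal,Salt,0.40
basal,Premix,0.50
BL-1,Corn,57.18
BL-1,Soybean meal,10.97
BL-1,Barley-1,28.90
BL-1,Dicalcium phosphate,1.05
BL-1,Limestone,1.00
BL-1,Salt,0.40
BL-1,Premix,0.50
BL-2,Corn,57.18
BL-2,Soybean meal,10.97
BL-2,Barley-2,28.90
BL-2,Dicalcium phosphate,1.05
BL-2,Limestone,1.00
BL-2,Salt,0.40
BL-2,Premix,0.50
BL-3,Corn,57.18
BL-3,Soybean meal,10.97
BL-3,Barley-3,28.90
BL-3,Dicalcium phosphate,1.05
BL-3,Limestone,1.00
BL-3,Salt,0.40
BL-3,Premix,0.50
BL-4,Corn,57.18
BL-4,Soybean meal,10.97
BL-4,Barley-4,28.90
BL-4,Dicalcium phosphate,1.05
BL-4,Limestone,1.00
BL-4,Salt,0.40
BL-4,Premix,0.50
BL-5,Corn,57.18
BL-5,Soybean meal,10.97
BL-5,Barley-5,28.90
BL-5,Dicalcium phosphate,1.05
BL-5,Limestone,1.00
BL-5,Salt,0.40
BL-5,Premix,0.50
BL-6,Corn,57.18
BL-6,Soybean meal,10.97
BL-6,Barley-6,28.90
BL-6,Dicalcium phosphate,1.05
BL-6,Limestone,1.00
BL-6,Salt,0.40
BL-6,Premix,0.50
BL-7,Corn,57.18
BL-7,Soybean meal,10.97
BL-7,Barley-7,28.90
BL-7,Dicalcium phosphate,1.05
BL-7,Limestone,1.00
BL-7,Salt,0.40
BL-7,Premix,0.50
BL-8,Corn,57.18
BL-8,Soybean meal,10.97
BL-8,Barley-8,28.90
BL-8,Dicalcium phosphate,1.05
BL-8,Limestone,1.00
BL-8,Salt,0.40
BL-8,Premix,0.50
BL-9,Corn,57.18
BL-9,Soybean meal,10.97
BL-9,Barley-9,28.90
BL-9,Dicalcium phosphate,1.05
BL-9,Limestone,1.00
BL-9,Salt,0.40
BL-9,Premix,0.50
BL-10,Corn,57.18
BL-10,Soybean meal,10.97
BL-10,Barley-10,28.90
BL-10,Dicalcium phosphate,1.05
BL-10,Limestone,1.00
BL-10,Salt,0.40
BL-10,Premix,0.50
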