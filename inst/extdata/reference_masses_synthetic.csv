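organ,age,sex,part,mass_g
heart,1,both,wall,50
heart,1,both,contents,48
heart,18,male,wall,330
heart,18,male,contents,510
heart,18,female,wall,250
heart,18,female,contents,370
stomach,1,both,wall,47
stomach,1,both,contents,40
stomach,18,male,wall,150
stomach,18,male,contents,250
stomach,18,female,wall,140
stomach,18,female,contents,230
kidneys,1,both,cortex,50
kidneys,1,both,medulla,18
kidneys,1,both,pelvis,2
kidneys,18,male,cortex,218
kidneys,18,male,medulla,78
kidneys,18,male,pelvis,14
kidneys,18,female,cortex,192
kidneys,18,female,medulla,69
kidneys,18,female,pelvis,14
liver,1,both,whole,330
liver,18,male,whole,1800
liver,18,female,whole,1400
lungs,1,both,whole,150
lungs,18,male,whole,1200
lungs,18,female,whole,950
brain,1,both,whole,950
brain,18,male,whole,1450
brain,18,female,whole,1300
pancreas,1,both,whole,20
pancreas,18,male,whole,140
pancreas,18,female,whole,120
thyroid,1,both,whole,1.8
thyroid,18,male,whole,20
thyroid,18,female,whole,17
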