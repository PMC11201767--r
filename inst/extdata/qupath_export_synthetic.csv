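"Image","Centroid X µm","Centroid Y µm","Nucleus: Area µm^2","Nucleus: 53BP1 mean","Cytoplasm: 53BP1 mean","Nucleus: p16 mean","Cytoplasm: p16 mean","Class"
"slideA",12.5,33.0,48.7,102.3,21.0,44.1,17.2,"53BP1-positive"
"slideA",210.4,87.2,54.2,18.9,12.3,20.5,14.8,"53BP1-negative"
"slideA",305.0,150.6,27.4,22.1,10.9,18.0,12.1,"53BP1-negative"
"slideA",402.8,220.9,81.3,131.7,25.4,60.3,19.9,"53BP1-positive"
"slideA",97.1,301.5,31.8,16.4,9.8,15.2,11.4,"53BP1-negative"
"slideA",155.9,410.2,66.0,24.7,13.1,22.8,13.6,"53BP1-negative"
"slideA",260.3,498.8,44.9,95.8,19.7,51.6,18.3,"53BP1-positive"
"slideA",350.6,590.1,58.5,20.2,11.5,19.4,12.9,"53BP1-negative"
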