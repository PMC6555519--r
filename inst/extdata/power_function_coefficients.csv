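response,family,a,b
proboscis,Andrenidae,1.06,0.96
proboscis,Apidae,2.15,0.96
proboscis,Colletidae,0.86,0.96
proboscis,Halictidae,1.37,0.96
proboscis,Megachilidae,1.87,0.96
proboscis,Melittidae,1.10,0.96
glossa,Andrenidae,0.23,1.04
glossa,Apidae,1.28,1.04
glossa,Colletidae,0.21,1.04
glossa,Halictidae,0.42,1.04
glossa,Megachilidae,1.17,1.04
glossa,Melittidae,0.29,1.04
prementum,Andrenidae,0.88,0.83
prementum,Apidae,0.91,0.75
prementum,Colletidae,0.56,1.14
prementum,Halictidae,0.89,1.05
prementum,Megachilidae,0.76,0.70
prementum,Melittidae,1.26,0.45
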