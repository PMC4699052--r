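"","snv1","snv2","snv3","snv4","snv5","snv6"
"person1","BB","AB","AB","AB","BB","BB"
"person2","BB","AB","AA","BB","BB","BB"
"person3","AB","AB","AB","AB","BB","BB"
"person4","BB","AB","BB","BB","AB","BB"
"person5","AB","AA","AB","BB","AB","BB"
"person6","BB","AB","BB","BB","AB","BB"
"person7","BB","AB","AB","AB","AB","BB"
"person8","BB","AA","BB","BB","BB","BB"
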