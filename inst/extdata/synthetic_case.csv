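"","snv1","snv2","snv3","snv4","snv5","snv6"
"person1","AB","AA","BB","AB","AA","BB"
"person2","BB","AB","BB","BB","BB","BB"
"person3","BB","AB","BB","AB","BB","AB"
"person4","AB","AA","AA","AA","BB","AB"
"person5","BB","AB","AB","BB","AB","AB"
"person6","BB","AB","AB","BB","AA","BB"
"person7","AB","BB","BB","BB","BB","BB"
"person8","AB","BB","BB","AA","BB","BB"
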