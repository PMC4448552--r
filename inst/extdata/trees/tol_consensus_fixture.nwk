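((((((Vertebrata:1,Cephalochordata:1)Chordata:1,(Echinodermata:1,Arthropoda:1)n1:1)Bilateria:1,Cnidaria:2)Eumetazoa:1,Porifera:3)Metazoa:1,(Ichthyosporea:4,Fungi:4)Holomycota_like:1)Opisthokonta:1,((Amoebozoa:5,Rhodophyta:5)n2:1,Archaea:6)n3:1,Bacteria:7)root;
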