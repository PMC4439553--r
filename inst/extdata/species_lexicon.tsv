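name	taxon_id
Rattus norvegicus	10116
Rat	10118
Cat	9685
Rhesus monkey	9544
Monkey	9539
Rabbit	9986
Human	9606
Macaca fascicularis	9541
Mouse	10090
Chicken	9031
Guinea-pig	10141
Guinea pig	10141
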