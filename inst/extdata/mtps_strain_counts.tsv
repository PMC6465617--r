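species	n_genomes
Ba. subtilis	38
Bi. infantis	19
Bi. longum	35
Bi. lactis	22
Lb. acidophilus	20
Lb. bulgaricus	15
Lb. casei	33
Lb. fermentum	31
Lb. gasseri	25
Lb. helveticus	16
Lb. paracasei	52
Lb. plantarum	9
Lc. cremoris	25
Lc. lactis	61
Sc. thermophilus	43
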