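name,base_ma,top_ma
Visean,346.7,330.9
Serpukhovian,330.9,323.2
Bashkirian,323.2,315.2
Moscovian,315.2,307.0
Kasimovian,307.0,303.7
Gzhelian,303.7,298.9
Asselian,298.9,293.5
Sakmarian,293.5,290.1
Artinskian,290.1,283.5
Kungurian,283.5,273.0
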