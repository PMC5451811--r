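species_name,family
Eryopella lacustris,Eryopellidae
Eryopella fluminea,Eryopellidae
Rheobatrachoides torrens,Rheobatrachoididae
Limnerpeton palustre,Limnerpetontidae
Siltina vadosa,Siltinidae
Stagnops minutus,Stagnopidae
Gyrinophilus dubius,Gyrinophilidae
Torrentia saxatilis,Rheobatrachoididae
Stagnops gigas,Stagnopidae
Paralimnia tranquilla,Paralimniidae
Fluvites communis,Eryopellidae
Limnodytes parvus,Rheobatrachoididae
Phreatoherpeton cavicola,Limnerpetontidae
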