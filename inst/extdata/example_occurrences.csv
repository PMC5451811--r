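occurrence_no,accepted_name,taxon_group,early_interval,late_interval,lithology1,paleolng,paleolat,reference_no,is_lagerstatte,specimen_score
1,Eryopella lacustris,Temnospondyli,Serpukhovian,Serpukhovian,claystone,-12.4,2.3,r1,false,4
2,Eryopella lacustris,Temnospondyli,Bashkirian,Bashkirian,gray shale,-12.1,2.5,r1,false,5
3,Eryopella lacustris,Temnospondyli,Kasimovian,Kasimovian,mudstone,-11.8,2.9,r2,false,
4,Eryopella fluminea,Temnospondyli,Bashkirian,Bashkirian,sandstone,14.2,-8.1,r2,false,2
5,Eryopella fluminea,Temnospondyli,Gzhelian,Gzhelian,cross-stratified sandstone,14.9,-7.7,r3,false,1
6,Rheobatrachoides torrens,Salientia,Asselian,Asselian,conglomerate,30.4,11.2,r3,false,1
7,Rheobatrachoides torrens,Salientia,Artinskian,Artinskian,coarse gravel,31.1,11.9,r3,false,
8,Limnerpeton palustre,Lepospondyli,Moscovian,Moscovian,coal,-44.9,-1.2,r4,true,5
9,Limnerpeton palustre,Lepospondyli,Moscovian,Moscovian,coal,-44.9,-1.2,r4,true,5
10,Limnerpeton palustre,Lepospondyli,Kasimovian,Kasimovian,marl,-44.2,-1.5,r5,false,4
11,Siltina vadosa,Urodela,Sakmarian,Sakmarian,siltstone,2.2,40.3,r5,false,3
12,Siltina vadosa,Urodela,Kungurian,Kungurian,laminated siltstone,2.6,41.0,r5,false,
13,Stagnops minutus,Allocaudata,Gzhelian,Gzhelian,lignite,-3.0,-3.0,r6,false,5
14,Eryops cf. megacephalus,Temnospondyli,Asselian,Asselian,mudstone,10.0,10.0,r6,false,
15,Andrias davidianus,Urodela,Kungurian,Kungurian,claystone,100.2,30.5,r6,false,
16,Phreatoherpeton cavicola,Lepospondyli,Artinskian,Artinskian,cave infill,-20.5,15.8,r7,false,
17,Gyrinodon dubius,other,Visean,Serpukhovian,,-60.1,-22.4,r7,false,
18,Torrentia saxatilis,Salientia,Moscovian,Kasimovian,breccia,55.0,5.5,r8,false,1
19,Stagnops gigas,Allocaudata,Visean,Visean,diatomite,-3.4,-2.1,r8,true,5
20,Stagnops gigas,Allocaudata,Bashkirian,Bashkirian,tuff,-2.9,-2.6,r8,false,4
21,Stagnops gigas,Allocaudata,Asselian,Asselian,claystone,-2.2,-2.8,r2,false,
22,Paralimnia tranquilla,Gymnophiona,Kasimovian,Kasimovian,dolomite,77.7,-33.3,r9,false,3
23,Fluvites communis,Temnospondyli,Sakmarian,Sakmarian,fine sandstone,-100.0,48.8,r9,false,2
24,Fluvites communis,Temnospondyli,Artinskian,Kungurian,sandstone,-99.1,49.2,r9,false,2
25,Limnodytes parvus,Salientia,Gzhelian,Gzhelian,phosphorite,20.0,0.5,r10,false,
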