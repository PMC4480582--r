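"cell_id","true_label","pRaf","ppMek","ppErk"
1,"EGF.wt",16.5145234678531,43.1116874469076,271.209854051777
2,"NGF.wt",72.9677481556129,124.652098067175,355.281554032767
3,"NGF.wt",105.477025332543,139.192851866993,322.486451945464
4,"NGF.wt",100.999920643301,175.052917395965,399.552695504063
5,"NGF.wt",55.5278737109894,106.243802748582,303.804362349118
6,"NGF.wt",78.642181874172,146.34099220583,338.461048211466
7,"EGF.wt",15.6233383988563,45.4675785463523,288.986615432836
8,"NGF.wt",70.8825354803114,131.458506424538,439.091601480649
9,"EGF.wt",15.2773306602591,35.7637525856816,182.031136509646
10,"EGF.wt",13.299983492667,49.7757261156729,258.506551408639
11,"EGF.wt",20.3748800089509,48.9881119063808,151.995898731186
12,"NGF.wt",53.3840214490551,138.950368480423,243.684522374796
13,"EGF.wt",11.6341291177749,55.1867348763563,340.701349021978
14,"EGF.wt",16.6430840910612,50.45723216016,195.285966257345
15,"NGF.wt",82.211011434554,131.1048550786,310.888815259003
16,"EGF.wt",13.3669423369747,57.7350130216167,183.115101040129
17,"EGF.wt",11.1620065130855,44.7083821542271,202.98652872624
18,"EGF.wt",13.3365713541001,38.4759600937043,231.900028158068
19,"NGF.wt",67.253597608461,98.005490655354,218.963296035768
20,"EGF.wt",11.2207360638844,50.1464120753166,252.373834687511
21,"NGF.wt",67.3256951556488,104.460112577477,336.007263262268
22,"NGF.wt",105.509864860198,151.427005709709,331.142805334181
23,"EGF.wt",13.0373712373759,55.2358682778944,172.178246841372
24,"EGF.wt",15.4210527391122,46.1956255653064,323.26262540241
25,"EGF.wt",7.87562324631715,23.6236215590174,145.836765851043
26,"NGF.wt",72.5140014048932,127.992122845498,354.892231182944
27,"EGF.wt",17.5955613308759,47.1487725020649,164.767662257792
28,"NGF.wt",102.592949087679,122.919695677478,231.695086901739
29,"EGF.wt",15.4585941543502,48.3063280551262,296.729153559717
30,"NGF.wt",59.6137734028847,132.553875333335,322.355738668267
31,"EGF.wt",14.3928588367549,50.0972817705862,313.721251514622
32,"NGF.wt",94.8023286236839,166.288345822255,434.318466753708
33,"EGF.wt",12.7933913251629,46.7271727028577,303.979027067401
34,"EGF.wt",12.7898147018138,52.9539923919513,299.41279061871
35,"NGF.wt",87.7476554140161,147.822408635496,430.261287094744
36,"NGF.wt",79.1552470139023,115.48322346664,326.456376904769
37,"EGF.wt",12.4020043841175,52.0789731376797,253.66588081297
38,"NGF.wt",95.893349766736,179.008305918089,329.798606989515
39,"NGF.wt",61.0805726905991,88.6123857378161,367.333261744002
40,"NGF.wt",77.9539300947928,128.34752844576,310.934487056667
41,"EGF.wt",12.8475907570378,44.4389220568518,226.200681861512
42,"EGF.wt",14.3467534320122,23.9574895635948,141.239599010695
43,"EGF.wt",10.8509192111366,35.3299373643151,230.537770221307
44,"EGF.wt",14.4652743912277,48.4086617359637,224.248653582915
45,"NGF.wt",77.9396132991923,163.001194292443,470.588267384727
46,"EGF.wt",12.8896142746222,51.630278062526,269.887792571834
47,"NGF.wt",105.580978922249,156.922982770191,368.268112925621
48,"NGF.wt",84.6750831999908,95.754270772482,359.088606729358
49,"NGF.wt",86.7600242887496,89.3974667763862,258.152677391979
50,"NGF.wt",109.964632584138,95.1948777799452,340.688594771556
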