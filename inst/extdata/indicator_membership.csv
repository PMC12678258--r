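no,indicator,cri,peoples,sendai,novel,dimension
1,Emergency medical facilities,1,1,1,0,Medical
2,Telemedicine infrastructure,0,0,0,1,Medical
3,Community health surveillance systems,0,0,1,1,Medical
4,Contact tracing capabilities,0,0,0,1,Medical
5,Isolation facility capacity,1,0,1,0,Medical
6,Personal protective equipment stockpiles,0,1,1,0,Medical
7,Emergency mental health support,0,0,0,1,Medical
8,Distributed medical resource networks,0,0,0,1,Medical
9,Community health worker capacity,1,1,0,0,Medical
10,Public health emergency protocols,1,1,1,0,Medical
11,Flexible space utilization capacity,0,0,0,1,Spatial
12,Digital infrastructure for remote activities,0,0,0,1,Spatial
13,Multi-functional public facilities,1,0,0,1,Spatial
14,Physical distancing-compatible design,0,0,0,1,Spatial
15,Ventilation systems in public spaces,0,0,0,1,Spatial
16,Transportation infrastructure resilience,1,1,1,0,Spatial
17,Emergency supply distribution networks,1,0,1,0,Spatial
18,Water and sanitation infrastructure,1,1,1,0,Spatial
19,Energy system redundancy,1,0,1,0,Spatial
20,Communication network reliability,1,1,1,0,Spatial
21,Social cohesion and mutual aid networks,1,1,0,0,Community
22,Vulnerable population support systems,1,1,1,0,Community
23,Community engagement mechanisms,1,1,0,0,Community
24,Risk communication channels,1,1,1,0,Community
25,Digital literacy and access,0,0,0,1,Community
26,Food security systems,1,1,1,0,Community
27,Economic support mechanisms,1,1,0,0,Community
28,Community leadership capacity,1,1,0,0,Community
29,Educational continuity systems,0,0,0,1,Community
30,Cultural adaptation strategies,0,1,0,1,Community
31,Green space accessibility during restrictions,0,0,0,1,Landscape
32,Outdoor recreation infrastructure,1,0,0,1,Landscape
33,Urban greenery for air quality,0,1,0,1,Landscape
34,Natural hazard mitigation,1,1,1,0,Landscape
35,Biodiversity and ecosystem health,0,1,0,0,Landscape
36,Climate adaptation measures,1,1,1,0,Landscape
37,Waste management systems,1,1,1,0,Landscape
38,Environmental monitoring capacity,0,1,1,0,Landscape
39,One Health integration,0,0,0,1,Landscape
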