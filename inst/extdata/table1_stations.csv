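station,latitude,longitude,habitat_100m,habitat_station,wetland_area,d2hf_mean,d2hf_sd,n,reclaimed
1,56.981,-111.619,Broadleaf,Exposed Land,13750,-136,23,14,FALSE
2,57.006,-111.608,Coniferous,Exposed Land,5000,-159,,1,TRUE
3,57.022,-111.637,Mixedwood,Exposed Land,7500,-147,17,32,TRUE
4,57.169,-111.536,Wetland,Wetland-Shrub,13125,-155,3,2,FALSE
5,57.044,-111.538,Mixedwood,Exposed Land,2500,-147,15,4,FALSE
6,57.247,-111.595,Mixedwood,Wetland-Shrub,0,-146,,1,FALSE
7,55.616,-111.041,Coniferous,Broadleaf,8125,-130,27,4,FALSE
8,57.169,-111.038,Wetland,Water,21875,-150,3,4,FALSE
9,57.080,-111.689,Wetland,Shrub-Tall,21875,-136,13,10,FALSE
10,57.248,-111.735,Mixedwood,Water,20625,-138,14,14,FALSE
11,57.240,-111.735,Mixedwood,Coniferous,15625,-144,4,5,FALSE
12,56.201,-110.893,Mixedwood,Coniferous,13750,-123,26,4,FALSE
13,56.997,-111.554,Mixedwood,Broadleaf,0,-136,,1,FALSE
14,57.382,-111.885,Broadleaf,Wetland-Shrub,8750,-138,8,5,FALSE
15,57.393,-111.983,Mixedwood,Broadleaf,11250,-143,4,7,FALSE
16,56.419,-111.375,Broadleaf,Wetland-Treed,5625,-149,4,2,FALSE
17,56.697,-111.398,Broadleaf,Coniferous,9375,-140,,1,FALSE
18,57.301,-111.217,Mixedwood,Broadleaf,15000,-142,11,2,FALSE
19,57.209,-111.692,Mixedwood,Broadleaf,23750,-145,7,4,FALSE
20,55.536,-110.889,Broadleaf,Coniferous,10000,-136,,1,FALSE
21,57.313,-111.212,Coniferous,Broadleaf,10000,-144,6,4,FALSE
22,57.181,-111.584,Broadleaf,Coniferous,625,-142,,1,FALSE
23,57.197,-111.046,Broadleaf,Wetland-Shrub,0,-137,10,6,FALSE
24,56.916,-111.458,Broadleaf,Wetland-Shrub,11250,-150,10,12,FALSE
25,56.924,-111.503,Coniferous,Broadleaf,1250,-149,7,5,FALSE
26,57.155,-111.063,Broadleaf,Coniferous,0,-141,4,7,FALSE
27,57.040,-111.596,Broadleaf,Exposed Land,1250,-162,10,5,TRUE
28,55.390,-110.744,Broadleaf,Coniferous,0,-138,,1,FALSE
29,55.571,-110.903,Broadleaf,Wetland-Treed,625,-124,22,2,FALSE
30,56.190,-110.973,Broadleaf,Broadleaf,0,-141,,1,FALSE
31,57.198,-111.531,Broadleaf,Broadleaf,4375,-146,3,3,FALSE
32,57.257,-111.041,Broadleaf,Coniferous,5000,-148,7,5,FALSE
33,55.429,-114.829,Coniferous,Wetland-Shrub,1250,-150,9,22,FALSE
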