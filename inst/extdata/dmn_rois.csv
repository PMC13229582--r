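label,region,hemisphere
1,frontal_superior_medial,left
2,frontal_superior_medial,right
3,frontal_medial_orbital,left
4,frontal_medial_orbital,right
5,cingulate_anterior,left
6,cingulate_anterior,right
7,cingulate_posterior,left
8,cingulate_posterior,right
9,precuneus,left
10,precuneus,right
11,angular_gyrus,left
12,angular_gyrus,right
13,temporal_middle,left
14,temporal_middle,right
15,hippocampus,left
16,hippocampus,right
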