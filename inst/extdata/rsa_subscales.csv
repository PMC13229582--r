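item,subscale
1,family_cohesion
2,family_cohesion
3,family_cohesion
4,family_cohesion
5,family_cohesion
6,family_cohesion
7,social_competence
8,social_competence
9,social_competence
10,social_competence
11,social_competence
12,social_competence
13,social_resources
14,social_resources
15,social_resources
16,social_resources
17,social_resources
18,social_resources
19,personal_strength
20,personal_strength
21,personal_strength
22,personal_strength
23,personal_strength
24,personal_strength
25,future_structured_style
26,future_structured_style
27,future_structured_style
28,future_structured_style
29,future_structured_style
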