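percentile,height_male,height_female
3,163,150.8437
5,164.6832,152.3686
10,167.2751,154.7168
25,171.6059,158.6405
50,176.4179,163
75,181.2298,167.3595
90,185.5606,171.2832
95,188.1525,173.6314
97,189.8357,175.1563
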