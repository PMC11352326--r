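Sex,Agemos,P3,P5,P10,P25,P50,P75,P90,P95,P97
1,228,162.4,164.1,166.7,171.0,175.8,180.6,185.0,187.6,189.2
2,228,150.5,152.0,154.4,158.3,162.7,167.0,171.0,173.3,174.9
1,240,163,164.6832,167.2751,171.6059,176.4179,181.2298,185.5606,188.1525,189.8357
2,240,150.8437,152.3686,154.7168,158.6405,163,167.3595,171.2832,173.6314,175.1563
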