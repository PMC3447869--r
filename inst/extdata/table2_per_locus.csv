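locus,population,allele_count,expected_het
Cervid1,finland,6,0.719
INRA011,finland,4,0.646
N,finland,7,0.805
Q,finland,7,0.777
ETH152,finland,6,0.796
BM203,finland,8,0.799
K,finland,2,0.497
BL25,finland,4,0.484
BM6438,finland,4,0.678
O,finland,3,0.543
BM848,finland,6,0.748
BM6506,finland,5,0.677
D,finland,7,0.720
OarFCB193,finland,6,0.797
Cervid1,oklahoma,14,0.847
INRA011,oklahoma,5,0.667
N,oklahoma,13,0.876
Q,oklahoma,15,0.861
ETH152,oklahoma,8,0.800
BM203,oklahoma,12,0.742
K,oklahoma,3,0.452
BL25,oklahoma,4,0.593
BM6438,oklahoma,9,0.790
O,oklahoma,4,0.509
BM848,oklahoma,10,0.829
BM6506,oklahoma,9,0.787
D,oklahoma,9,0.824
OarFCB193,oklahoma,12,0.809
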