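synthetic Finland-like genotypes (HWE draw, not real data)
Cervid1
INRA011
N
Q
ETH152
BM203
K
BL25
BM6438
O
BM848
BM6506
D
OarFCB193
Pop
synthetic_finland_like_1 ,  004001 002001 006005 001002 002003 001003 001002 002001 001002 001003 005003 004003 001004 000000
synthetic_finland_like_2 ,  005002 001001 003002 002001 002003 002006 002002 001001 001003 002002 005004 003005 002001 002006
synthetic_finland_like_3 ,  001001 001002 003005 001001 001001 003002 002002 001002 002003 001001 001001 002005 001003 002002
synthetic_finland_like_4 ,  003006 002002 001002 001007 001006 002005 001001 001001 003004 001001 002002 003001 003002 000000
synthetic_finland_like_5 ,  002001 000000 002001 002001 000000 005001 002002 001001 002001 001002 002002 004002 001002 004003
synthetic_finland_like_6 ,  002005 002001 001002 002001 006003 001002 001002 001001 002003 002002 001001 001003 004001 001001
synthetic_finland_like_7 ,  003004 001003 002007 001002 002003 008001 002001 002002 002001 000000 002001 001001 001002 003006
synthetic_finland_like_8 ,  001002 001004 002002 001001 005005 001004 001002 001001 001001 001001 001001 001001 001003 005002
synthetic_finland_like_9 ,  002005 001001 001001 002001 004002 001003 001001 001001 004002 000000 001004 003001 003001 006003
synthetic_finland_like_10 ,  003002 001002 001001 006001 004001 002001 001001 002001 004002 001001 002001 003001 001003 001001
synthetic_finland_like_11 ,  000000 002003 004003 001005 005001 001002 002002 001001 001002 001001 001002 001002 001001 004005
synthetic_finland_like_12 ,  003001 001002 002003 001003 001002 003002 001001 001001 004001 003001 005003 001004 002002 000000
synthetic_finland_like_13 ,  005001 001002 002002 001001 000000 001003 002002 004002 003003 003001 002001 002004 002001 001004
synthetic_finland_like_14 ,  000000 004004 002001 002002 002001 004003 001002 001001 002003 003001 002002 001004 002001 003002
synthetic_finland_like_15 ,  002001 004003 002002 001001 003003 001002 001001 001002 002001 001002 003003 001003 001001 000000
synthetic_finland_like_16 ,  005003 000000 001005 000000 002006 001001 001001 001003 002002 001001 002001 004001 001004 004002
synthetic_finland_like_17 ,  006002 001003 005003 001004 002001 001001 002001 001001 001002 001003 005002 001001 001001 003002
synthetic_finland_like_18 ,  001001 002001 003002 002003 002001 004003 001001 001001 000000 002003 001005 001001 001001 002001
synthetic_finland_like_19 ,  002001 002002 000000 002001 004001 002006 001001 001001 002004 002002 001002 002001 003003 001005
synthetic_finland_like_20 ,  002002 002002 004005 003001 001004 001005 001001 001001 001001 002003 002005 002003 001001 001003
synthetic_finland_like_21 ,  004002 002001 000000 003002 002003 001002 001002 001001 003003 003002 001006 001002 001004 001001
synthetic_finland_like_22 ,  001006 001001 005001 001002 001002 002001 001002 003001 003002 001002 003003 001002 001001 005003
synthetic_finland_like_23 ,  006003 001001 002003 001001 004002 008005 001001 001001 001001 000000 001001 001001 002001 001003
synthetic_finland_like_24 ,  005002 001003 001007 006001 002001 004001 002001 001002 003002 003001 001001 001001 003001 001001
synthetic_finland_like_25 ,  001004 004002 004001 002005 001003 002001 001002 001001 001003 003002 001001 002003 002001 002002
synthetic_finland_like_26 ,  002001 004003 004005 001006 001004 001003 002002 001002 003002 001001 006004 004001 001001 003003
synthetic_finland_like_27 ,  000000 002001 006001 005002 006001 002001 002002 004001 002001 001001 001001 001001 004002 005004
synthetic_finland_like_28 ,  004003 002004 004001 001001 002006 002001 001001 004001 001001 002002 001001 001002 001001 001002
synthetic_finland_like_29 ,  002003 002001 001001 005001 004001 003002 002001 001002 003001 000000 001002 002002 000000 000000
synthetic_finland_like_30 ,  004001 001001 001001 005001 005001 002005 001001 002001 001002 001001 001001 001001 004004 003005
synthetic_finland_like_31 ,  003001 002002 001002 001001 002005 002002 001002 001001 002003 001002 001004 001001 003006 003003
synthetic_finland_like_32 ,  000000 003001 000000 004007 003002 002001 002001 002001 003003 000000 002004 001001 001001 001002
synthetic_finland_like_33 ,  001001 002002 001001 002002 001003 002006 001002 001001 001001 001002 001001 000000 003001 002006
synthetic_finland_like_34 ,  002002 001001 001001 001001 001001 001007 001001 004001 001002 001001 001004 004002 000000 006004
synthetic_finland_like_35 ,  001001 002002 001007 005001 004004 006002 000000 002001 001003 001001 002002 003001 001001 001001
synthetic_finland_like_36 ,  003003 002002 001004 001006 002002 000000 001001 001002 001002 001001 002003 003002 001002 003001
synthetic_finland_like_37 ,  001001 000000 002001 001001 003006 002003 001002 001001 001001 001001 001001 005002 002005 005004
synthetic_finland_like_38 ,  001001 001001 001005 002003 006005 001006 000000 001001 001001 001001 003002 000000 001002 000000
synthetic_finland_like_39 ,  004002 002001 004003 002005 002003 001001 001002 001002 001001 003002 005005 001002 002002 001001
synthetic_finland_like_40 ,  002001 003002 004002 002007 002001 002004 002002 001002 001002 003001 001002 001002 001001 001005
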