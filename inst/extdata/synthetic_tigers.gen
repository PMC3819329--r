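synthetic 6-population microsatellite dataset (simulated, seed 1)
L01
L02
L03
L04
L05
L06
L07
L08
L09
L10
L11
L12
L13
L14
Pop
MTR_01 ,  001002 004006 004006 001004 008011 002005 008009 002013 007008 003013 004004 002008 001015 006007
MTR_02 ,  002003 002004 004007 004007 005011 002005 008008 007008 007007 002013 001004 014014 011013 007011
MTR_03 ,  003003 003006 001004 004005 001004 005008 008008 004004 001007 003009 001004 002014 005008 007011
MTR_04 ,  002002 003004 006007 002003 011011 005005 008011 002013 008011 013013 004012 009014 005011 007009
MTR_05 ,  001002 003003 004006 004010 003011 005005 008008 012013 007007 013013 003004 008014 011011 005007
Pop
PTR_01 ,  003005 003004 001007 002007 011011 006012 001003 002004 007012 009013 013013 008014 007009 007012
PTR_02 ,  003003 003005 001005 002007 001001 005006 005011 004004 005009 009013 003014 008014 006013 004007
PTR_03 ,  002004 003005 001005 002002 008011 002002 004011 004007 005007 009013 003003 005009 006013 016016
PTR_04 ,  004005 004005 005006 002007 008011 005012 005008 004004 009013 005009 002002 005014 006009 003012
PTR_05 ,  002002 003004 005005 002002 011011 005006 004012 004007 009013 005009 010011 001005 006013 004016
PTR_06 ,  003004 003003 001005 002007 001011 000000 004011 004004 009013 005011 003010 002014 004009 001012
PTR_07 ,  003004 004005 005006 002002 007008 005005 008011 004011 005006 005013 003003 000000 006009 005006
Pop
NGWLS_01 ,  003004 003006 006007 005006 009011 005006 002002 004010 007007 007013 003012 003014 008014 000000
NGWLS_02 ,  004004 003006 004007 002007 005009 006012 006011 007012 004007 001013 001014 003013 012015 001004
NGWLS_03 ,  003003 003003 005006 000000 007009 005006 002002 008011 007007 001009 001005 003012 007008 001015
NGWLS_04 ,  003003 003004 001004 002004 000000 006008 002011 010011 008008 007009 001013 002013 015015 011016
NGWLS_05 ,  003004 003004 001005 002002 008011 001008 002002 007007 004007 001013 001009 002014 008013 002007
Pop
TATR_01 ,  002003 003004 006007 005005 003011 001005 002011 002004 009013 004009 003010 001009 008013 004005
TATR_02 ,  002003 001004 007007 005005 002010 007008 006008 002007 001007 002008 006014 001013 002015 005006
TATR_03 ,  002003 004004 006007 002005 003006 005005 008008 004013 001008 004013 003014 008008 005013 006006
TATR_04 ,  003004 004004 002002 005005 008008 006008 000000 002013 004007 003009 003010 001002 009014 006006
TATR_05 ,  002005 001004 007007 002002 003008 001008 008011 007013 001010 003009 001003 001008 006006 001006
TATR_06 ,  003003 004005 006007 005007 008008 005006 002008 003007 007010 003004 003010 008009 005015 005006
TATR_07 ,  003004 001003 002002 002002 001008 005005 008011 003012 005005 004009 003010 001009 011013 006006
TATR_08 ,  003005 004004 006006 002004 002011 002007 006009 007013 004007 003004 003003 009011 001002 001006
TATR_09 ,  003005 000000 006007 002007 002004 005008 001007 007013 007008 004004 003003 001013 013015 001010
TATR_10 ,  003003 004004 002006 002007 002006 006008 008008 004007 007011 003009 003014 001009 005009 001005
TATR_11 ,  003003 004004 004006 002005 001002 005006 008011 001007 004008 003009 003003 009013 005013 005005
TATR_12 ,  002003 004004 002007 002002 001011 002005 008009 007007 004004 011011 003005 001009 011013 006006
TATR_13 ,  003004 004004 001007 005005 002003 008008 007011 002007 005007 004008 003003 009009 013014 006006
TATR_14 ,  002004 004005 001007 002005 002003 001007 006008 007007 002007 004008 004014 001009 001015 006011
TATR_15 ,  003003 001004 001006 002005 003007 002007 001008 003013 007007 004004 005012 001014 002013 006006
TATR_16 ,  003003 004005 006007 001007 001010 001001 007008 013013 007007 004004 003010 008013 005008 006006
Pop
KTR_01 ,  003003 003003 001008 001002 007010 006006 008011 002004 007012 005008 013013 001013 009013 005011
KTR_02 ,  003003 003005 001006 004007 007010 008008 001002 002013 007008 003009 003012 001008 009015 005007
KTR_03 ,  003003 003004 001004 001002 007011 005006 008009 004007 007012 005005 003014 008008 009013 006007
KTR_04 ,  003004 003005 006008 002004 010011 004006 002008 002007 005012 005013 003014 014014 007009 003006
KTR_05 ,  004004 004004 004004 004004 001001 008008 005008 004007 005013 009009 001001 008010 008011 002004
KTR_06 ,  003005 004006 001007 001002 010011 004005 002011 002002 007012 008008 003014 003009 009013 007012
KTR_07 ,  003005 003003 004007 004010 011011 002005 011011 008013 007007 013013 004004 014014 011011 015016
KTR_08 ,  003003 005005 006007 002005 003011 005005 002008 002007 007009 005009 001003 003009 009009 008008
KTR_09 ,  003003 003005 002002 001002 001010 005006 008008 002007 007012 003008 003014 003003 015015 007008
KTR_10 ,  004004 003003 004004 002003 001007 006007 009011 002007 010010 001007 001001 002011 006008 003005
KTR_11 ,  002002 003003 004007 004007 007011 003005 000000 002013 007007 009009 000000 013014 007009 002005
KTR_12 ,  003003 003004 001001 001002 011011 006008 003008 004013 007012 002008 009014 001003 009013 005007
KTR_13 ,  002005 003005 001006 001002 007010 006012 003005 002010 005012 005009 001014 001007 008009 007008
KTR_14 ,  003003 005006 001006 002007 003011 003003 003008 002013 005007 005008 003005 001014 013015 003005
KTR_15 ,  003005 004004 001006 002004 004009 005006 003008 007013 005007 001009 012014 003014 007015 006007
Pop
NSTR_01 ,  004005 003004 000000 001004 007007 005006 001009 007007 001010 001007 001001 008008 013015 001014
NSTR_02 ,  004005 004004 001006 002002 007010 008008 001009 001002 005010 007013 010010 008008 006011 003003
NSTR_03 ,  003003 004006 004007 002004 001007 002006 011011 007011 007008 013013 001001 003014 006014 004006
NSTR_04 ,  003004 003004 006007 002002 007007 006012 008011 007011 001010 007009 010014 001008 005011 003014
NSTR_05 ,  004004 003004 006007 002002 007008 006007 005005 007011 013013 007013 003010 003008 005013 003004
NSTR_06 ,  004005 003004 004006 002002 001001 006006 001001 002007 002010 003007 010010 008013 008013 003014
NSTR_07 ,  003004 004006 001006 002002 001007 005005 011011 002007 008010 001003 001012 002008 005014 005005
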