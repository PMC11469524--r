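# stimuli: BCR
source,target
BCR,SYK
BCR,ZAP70
SYK,PI3K
ZAP70,PI3K
SYK,Btk
ZAP70,Btk
PI3K,Btk
PI3K,AKT
AKT,mTORC1
mTORC1,RPS6
ERK,RPS6
AKT,BAD
AKT,GSK3
ERK,GSK3
Btk,RAF
RAF,MEK
MEK,ERK
ERK,RAF
ERK,p90RSK
Btk,p38
p38,HSP27
Btk,JNK
JNK,cJun
Btk,IKK
IKK,NFkB
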