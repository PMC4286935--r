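SRPK1,ppi,A0SYN001
SRPK1,ppi,A0SYN002
SRPK1,ppi,A0SYN003
SRPK1,ppi,A0SYN004
SRPK1,ppi,A0SYN005
SRPK1,ppi,A0SYN006
SRPK1,ppi,A0SYN007
SRPK1,ppi,A0SYN008
SRPK1,ppi,A0SYN009
SRPK1,ppi,A0SYN010
SRPK1,ppi,A0SYN011
SRPK1,ppi,A0SYN012
SRPK1,ppi,A0SYN013
SRPK1,ppi,A0SYN014
SRPK1,ppi,A0SYN015
SRPK1,ppi,A0SYN016
SRPK1,ppi,A0SYN017
SRPK1,ppi,A0SYN018
SRPK1,ppi,A0SYN019
SRPK1,ppi,A0SYN020
SRPK1,ppi,A0SYN021
SRPK1,ppi,A0SYN022
SRPK1,ppi,A0SYN023
SRPK1,ppi,A0SYN024
SRPK1,ppi,A0SYN025
SRPK1,ppi,A0SYN026
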