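>SRPK1 preys (synthetic)
prey of SRPK1,A0SYN001,synthetic
prey of SRPK1,A0SYN002,synthetic
prey of SRPK1,A0SYN003,synthetic
prey of SRPK1,A0SYN004,synthetic
prey of SRPK1,A0SYN005,synthetic
prey of SRPK1,A0SYN006,synthetic
prey of SRPK1,A0SYN007,synthetic
prey of SRPK1,A0SYN008,synthetic
prey of SRPK1,A0SYN009,synthetic
prey of SRPK1,A0SYN010,synthetic
prey of SRPK1,A0SYN011,synthetic
prey of SRPK1,A0SYN012,synthetic
prey of SRPK1,A0SYN013,synthetic
prey of SRPK1,A0SYN014,synthetic
prey of SRPK1,A0SYN015,synthetic
prey of SRPK1,A0SYN016,synthetic
prey of SRPK1,A0SYN017,synthetic
prey of SRPK1,A0SYN018,synthetic
prey of SRPK1,A0SYN019,synthetic
prey of SRPK1,A0SYN020,synthetic
prey of SRPK1,A0SYN021,synthetic
prey of SRPK1,A0SYN022,synthetic
prey of SRPK1,A0SYN023,synthetic
prey of SRPK1,A0SYN024,synthetic
prey of SRPK1,A0SYN025,synthetic
prey of SRPK1,A0SYN026,synthetic
>SRPK2 preys (synthetic)
prey of SRPK2,A0SYN001,synthetic
prey of SRPK2,A0SYN002,synthetic
prey of SRPK2,A0SYN003,synthetic
prey of SRPK2,A0SYN004,synthetic
prey of SRPK2,A0SYN005,synthetic
prey of SRPK2,A0SYN006,synthetic
prey of SRPK2,A0SYN007,synthetic
prey of SRPK2,A0SYN008,synthetic
prey of SRPK2,A0SYN009,synthetic
prey of SRPK2,A0SYN010,synthetic
prey of SRPK2,A0SYN011,synthetic
prey of SRPK2,A0SYN012,synthetic
prey of SRPK2,A0SYN013,synthetic
prey of SRPK2,A0SYN014,synthetic
prey of SRPK2,A0SYN015,synthetic
prey of SRPK2,A0SYN016,synthetic
prey of SRPK2,A0SYN017,synthetic
prey of SRPK2,A0SYN018,synthetic
prey of SRPK2,B0SYN001,synthetic
prey of SRPK2,B0SYN002,synthetic
prey of SRPK2,B0SYN003,synthetic
prey of SRPK2,B0SYN004,synthetic
prey of SRPK2,B0SYN005,synthetic
prey of SRPK2,B0SYN006,synthetic
>SRPK3 preys (synthetic)
prey of SRPK3,A0SYN001,synthetic
prey of SRPK3,A0SYN002,synthetic
prey of SRPK3,A0SYN003,synthetic
prey of SRPK3,A0SYN004,synthetic
prey of SRPK3,C0SYN001,synthetic
prey of SRPK3,C0SYN002,synthetic
prey of SRPK3,C0SYN003,synthetic
prey of SRPK3,C0SYN004,synthetic
prey of SRPK3,C0SYN005,synthetic
prey of SRPK3,C0SYN006,synthetic
prey of SRPK3,C0SYN007,synthetic
prey of SRPK3,C0SYN008,synthetic
>PRPF4B preys (synthetic)
prey of PRPF4B,A0SYN025,synthetic
prey of PRPF4B,A0SYN026,synthetic
prey of PRPF4B,D0SYN001,synthetic
prey of PRPF4B,D0SYN002,synthetic
prey of PRPF4B,D0SYN003,synthetic
prey of PRPF4B,D0SYN004,synthetic
prey of PRPF4B,D0SYN005,synthetic
prey of PRPF4B,D0SYN006,synthetic
prey of PRPF4B,D0SYN007,synthetic
prey of PRPF4B,D0SYN008,synthetic
prey of PRPF4B,D0SYN009,synthetic
prey of PRPF4B,D0SYN010,synthetic
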