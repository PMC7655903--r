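mother,father,n_offspring
VGN,SRZ,55
VGN,BDG,57
VGN,71077-308,54
VGN,92510-1,32
VGN,72131-017,34
VGN,73182-009,14
VGN,73193-056,30
71041-3-402,BDG,28
71041-3-402,71077-308,11
71041-3-402,92510-1,17
71041-3-402,72145-007,30
71041-3-402,73182-009,25
71072-501,SRZ,25
71072-501,BDG,28
71072-501,71077-308,29
SSC,SRZ,15
SSC,BDG,20
SSC,71077-308,20
SSC,92510-1,22
71040,72145-007,24
71040,72131-017,20
662200037,72145-007,25
662200037,72131-017,32
662200037,73182-009,118
662200037,73193-056,31
73193-089,72131-017,22
73193-089,73182-009,20
73193-089,73193-056,18
662200216,73182-009,31
662200216,72131-036,19
71069-914,3824-3,22
73193-091,3824-3,21
73193-091,72146-11,30
H480,3824-3,13
H480,71034-2-406,19
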