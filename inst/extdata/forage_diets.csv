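diet_id,diet_name,cp,ndf,nsc,ee,ash,ivdmd,leucaena,leucaena_species
toledo,Toledo Grass,6.5,69.2,11.4,2.51,10.5,64.1,FALSE,
cayman,Cayman Grass,8.3,68.2,8.8,2.51,12.1,61.3,FALSE,
star_kudzu,Star Grass plus Kudzu (70:30),11.2,72.9,3.4,2.97,9.6,58.7,FALSE,
cayman_ldiv,Cayman Grass plus L. diversifolia (70:30),14.7,56.8,12.5,3.46,12.5,60.4,TRUE,L. diversifolia
cayman_lleu,Cayman Grass plus L. leucocephala (70:30),11.0,62.5,10.9,3.78,11.9,61.6,TRUE,L. leucocephala
toledo_can_ldiv,Toledo Grass plus Canavalia plus L. diversifolia (70:15:15),10.8,66.5,10.2,2.92,9.6,61.2,TRUE,L. diversifolia
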