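subject,session,behavior,out_of_sight
kiri,am,rest,0
kiri,am,rest,0
kiri,am,forage,0
kiri,am,groom,0
kiri,am,rest,0
kiri,am,,1
kiri,pm,rest,0
kiri,pm,forage,0
kiri,pm,play,0
kiri,pm,forage,0
tane,am,pace,0
tane,am,pace,0
tane,am,pace,0
tane,am,rest,0
tane,am,,1
tane,am,,1
tane,pm,pace,0
tane,pm,pace,0
tane,pm,rest,0
tane,pm,pace,0
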