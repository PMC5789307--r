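predicted,sound_grazing,sound_standing,sound_walking,sound_lying,lame_walking
sound_grazing,283,26,2,0,0
sound_standing,13,53,10,12,9
sound_walking,2,15,60,8,42
sound_lying,0,12,23,18,6
lame_walking,0,0,0,2,31
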