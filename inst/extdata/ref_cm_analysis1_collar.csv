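predicted,sound_grazing,sound_standing,sound_walking,sound_lying,lame_walking,lame_grazing
sound_grazing,281,26,0,0,0,39
sound_standing,12,53,12,3,29,14
sound_walking,0,22,77,13,13,2
sound_lying,2,5,5,22,4,4
lame_walking,0,0,0,1,11,4
lame_grazing,3,0,0,0,20,108
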