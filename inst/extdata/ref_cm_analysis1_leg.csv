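predicted,sound_grazing,sound_standing,sound_walking,sound_lying,lame_walking,lame_grazing
sound_grazing,262,34,0,0,5,55
sound_standing,33,71,0,0,6,105
sound_walking,0,0,81,0,2,0
sound_lying,2,0,0,46,0,8
lame_walking,1,0,13,0,80,6
lame_grazing,0,1,0,0,0,7
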