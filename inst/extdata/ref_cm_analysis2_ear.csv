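predicted,sound_grazing,sound_standing,sound_walking,lame_walking
sound_grazing,321,26,1,6
sound_standing,15,830,1,3
sound_walking,2,5,262,9
lame_walking,4,0,9,80
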