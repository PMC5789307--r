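predicted,sound_grazing,sound_standing,sound_walking,sound_lying,lame_walking
sound_grazing,266,44,0,0,3
sound_standing,26,61,0,0,6
sound_walking,0,0,60,0,3
sound_lying,0,0,0,46,0
lame_walking,6,1,34,0,81
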