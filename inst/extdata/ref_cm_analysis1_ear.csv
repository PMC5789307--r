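predicted,sound_grazing,sound_standing,sound_walking,lame_walking,lame_grazing
sound_grazing,287,42,5,6,131
sound_standing,44,812,2,3,11
sound_walking,1,4,241,9,3
lame_walking,0,0,14,78,3
lame_grazing,10,3,11,2,34
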