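quantity,hours
social_only,3239
complex_song_hws1,1127
preliminary_song_hws2,430
total_vocalization_hours,4796
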