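stream_id,t,kind
v0001,0,round_start
v0001,9,kill
v0001,34,death
v0001,45,kill
v0001,64,death
v0001,110,kill
v0001,119,round_end
v0001,120,round_start
v0001,194,death
v0001,239,round_end
v0001,240,round_start
v0001,263,kill
v0001,317,death
v0001,359,round_end
v0001,360,round_start
v0001,397,kill
v0001,447,kill
v0001,479,round_end
v0001,480,round_start
v0001,499,death
v0001,599,round_end
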