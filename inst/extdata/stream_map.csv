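stream_id,match_id,offset_s
v0001,m00001,0
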