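plate_id,condition,humidity_pct,temp_start_c,temp_end_c,duration_min
zero_01,zero,30.26691026,22.26591256,21.04704393,63.6387938
field1_01,field1,32.55996439,22.39547508,23.10209245,57.39266885
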