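plate_id,condition,count_target,count_control
magnet_001,magnet,21,28
magnet_002,magnet,35,32
magnet_003,magnet,33,39
magnet_004,magnet,31,24
magnet_005,magnet,25,28
magnet_006,magnet,22,24
control_001,control,34,30
control_002,control,32,23
control_003,control,31,27
control_004,control,21,29
control_005,control,33,41
control_006,control,23,20
diacetyl_001,diacetyl,48,7
diacetyl_002,diacetyl,60,3
diacetyl_003,diacetyl,67,7
diacetyl_004,diacetyl,58,3
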