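plate_id,condition,angle_deg
zero_01,zero,91.43531832
zero_01,zero,70.41163678
zero_01,zero,318.8060902
zero_01,zero,111.7941665
zero_01,zero,82.62080801
zero_01,zero,147.7015599
zero_01,zero,249.1436153
zero_01,zero,327.7945017
zero_01,zero,200.4873064
zero_01,zero,167.9622327
zero_01,zero,153.46153
zero_01,zero,133.8532914
zero_01,zero,84.38738204
zero_01,zero,46.39491293
zero_01,zero,79.68349697
zero_01,zero,11.23306358
zero_01,zero,61.80795589
field1_01,field1,224.4390703
field1_01,field1,188.7702346
field1_01,field1,275.6800086
field1_01,field1,299.191
field1_01,field1,237.5381128
field1_01,field1,274.7190759
field1_01,field1,217.2255703
field1_01,field1,203.8574401
field1_01,field1,339.5027607
field1_01,field1,339.5895433
field1_01,field1,313.8622671
field1_01,field1,93.26880762
field1_01,field1,355.5206088
field1_01,field1,266.414233
field1_01,field1,327.899208
field1_01,field1,255.6237222
field1_01,field1,271.795551
field1_01,field1,288.7422082
field1_01,field1,349.4412554
field1_01,field1,351.2208488
field1_01,field1,317.1614326
field1_01,field1,54.93862113
field1_01,field1,338.651187
field1_01,field1,274.7979908
field1_01,field1,15.73403341
field1_01,field1,316.0576498
field1_01,field1,331.8600385
field1_01,field1,259.5511888
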