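subject_id,time,state
s0001,0,1
s0001,2.758,2
s0001,4.6766,2
s0001,7.6883,2
s0001,11.0702,2
s0001,11.2488,2
s0001,13.6765,2
s0002,0,1
s0002,0.2486,1
s0002,2.0554,3
s0003,0,1
s0003,0.2662,1
s0003,4.2793,1
s0003,5.6365,1
s0003,8.3837,1
s0003,12.3605,1
s0004,0,1
s0004,0.066,1
s0004,4.1037,1
s0004,7.3314,1
s0004,10.5772,2
s0004,13.0257,2
s0005,0,1
s0005,1.5478,1
s0005,3.8643,1
s0005,5.2124,1
s0005,8.8109,1
s0005,10.7695,2
s0005,11.4278,2
s0005,12.9516,2
s0006,0,1
s0006,1.2214,1
s0006,1.5499,1
s0006,4.1778,2
s0006,6.6433,2
s0006,7.094,2
s0006,9.9117,2
s0006,13.9016,2
s0007,0,1
s0007,1.3102,1
s0007,2.9596,1
s0007,3.8579,1
s0007,5.7255,1
s0007,9.4336,2
s0007,12.3207,2
s0007,12.3506,2
s0007,13.0111,2
s0007,13.547,2
s0008,0,1
s0008,2.3277,3
s0009,0,1
s0009,3.9717,1
s0009,8.1598,2
s0009,10.8212,2
s0009,13.7812,3
s0010,0,1
s0010,0.5148,1
s0010,4.7099,2
s0010,6.547,2
s0010,7.2975,2
s0010,8.1366,2
s0010,11.3957,3
s0011,0,1
s0011,3.3023,1
s0011,6.9225,3
s0012,0,1
s0012,1.8344,1
s0012,3.8342,1
s0012,7.3689,2
s0012,8.1567,2
s0012,11.7138,3
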