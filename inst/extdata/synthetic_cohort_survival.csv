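patient_id,time,event
sim1,18.976063066005054,1
sim2,22.148777870461345,0
sim3,19.129606216736168,1
sim4,19.428501026704907,0
sim5,29.872437863776508,1
sim6,16.760772812138327,1
sim7,23.392705168742111,1
sim8,20.498933903872967,0
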