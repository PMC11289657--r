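patient_id,intercept,z
sim1,1,-0.71178404856951361
sim2,1,-0.014303230585372617
sim3,1,0.71621359971731058
sim4,1,-0.14578751201383078
sim5,1,0.56203451460392206
sim6,1,0.24333434106320606
sim7,1,0.23009064738255661
sim8,1,-0.095876536969328907
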