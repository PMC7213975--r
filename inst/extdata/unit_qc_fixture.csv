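unit_id,isolation_distance,isi_contamination,expected_accepted
u1,25,0.0005,TRUE
u2,15,0.0000,FALSE
u3,20,0.0005,FALSE
u4,25,0.0010,TRUE
u5,25,0.0011,FALSE
u6,1000,0.0000,TRUE
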