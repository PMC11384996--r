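"participant_id","trial_index","stimulus_id","mss","vss","context_present","target_present","response","rt","correct"
"p001",1,"stim_099",4,8,TRUE,TRUE,"present",5.8353539074789,TRUE
"p001",2,"stim_106",8,8,FALSE,FALSE,"absent",3.17035390747896,TRUE
"p001",3,"stim_062",1,4,FALSE,TRUE,"present",0.750353907478995,TRUE
"p001",4,"stim_098",2,8,FALSE,FALSE,"absent",1.090353907479,TRUE
"p001",5,"stim_102",4,8,FALSE,TRUE,"present",2.11535390747898,TRUE
"p001",6,"stim_032",1,2,FALSE,FALSE,"absent",0.800353907478995,TRUE
"p001",7,"stim_013",2,1,TRUE,TRUE,"present",1.365353907479,TRUE
"p001",8,"stim_020",4,1,FALSE,FALSE,"absent",0.685353907478995,TRUE
"p001",9,"stim_100",4,8,FALSE,FALSE,"absent",3.33535390747896,TRUE
"p001",10,"stim_031",1,2,TRUE,TRUE,"present",1.53535390747899,TRUE
"p001",11,"stim_068",2,4,FALSE,TRUE,"present",1.58035390747899,TRUE
"p001",12,"stim_009",2,1,TRUE,TRUE,"present",0.625353907478995,TRUE
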