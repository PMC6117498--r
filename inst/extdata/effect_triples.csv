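comparison,label,group1,group2,delta_u,cohen_d,t
acute_vs_chronic,S,acute,chronic,0.216,1.58,229.75
acute_vs_chronic,CS,acute,chronic,-0.038,-0.29,-42.01
acute_vs_chronic,F,acute,chronic,-0.098,-0.68,-99.26
acute_vs_chronic,DAP,acute,chronic,-0.078,-0.55,-80.09
mild_vs_serious,ME,mild,serious,0.039,0.25,8.33
mild_vs_serious,OP,mild,serious,0.060,0.57,18.75
mild_vs_serious,PP,mild,serious,0.132,1.19,39.33
mild_vs_serious,S,mild,serious,0.274,1.91,62.82
mild_vs_serious,MC,mild,serious,-0.165,-0.99,-32.58
mild_vs_serious,MAP,mild,serious,-0.082,-0.65,-21.45
mild_vs_serious,F,mild,serious,-0.018,-0.26,-8.45
mild_vs_serious,DAP,mild,serious,-0.229,-1.55,-50.93
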