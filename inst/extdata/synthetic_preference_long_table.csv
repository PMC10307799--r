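Fish ID,Condition,Period,Time A (s),Time B (s)
1M,Chasing-vs-Motionless,1,1100,1050
1M,Chasing-vs-Motionless,2,1900,420
1M,Chasing-vs-Motionless,3,1180,990
2M,Chasing-vs-Motionless,1,980,1010
2M,Chasing-vs-Motionless,2,1700,510
2M,Chasing-vs-Motionless,3,1040,1080
1M,Absent-vs-Absent,1,1020,1060
1M,Absent-vs-Absent,2,1010,990
1M,Absent-vs-Absent,3,990,1030
2M,Absent-vs-Absent,1,1005,995
2M,Absent-vs-Absent,2,960,1030
2M,Absent-vs-Absent,3,1015,1000
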