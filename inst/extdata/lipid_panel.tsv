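# Synthetic 124-species targeted plasma lipid panel (Biocrates p180-style).
# Class counts: PC 50 > LPC 22 >= SM 20 > PC O- 18 > CAR 14.
# baseline_log2: log2 median control concentration (uM), set from class-typical
# plasma ranges (PC ~16-256, LPC ~6-90, SM ~4-64, PC O- ~0.7-11, CAR ~0.1-2 uM);
# synthetic values, not measured in any cohort.
name	lipid_class	baseline_log2
PC 24:0	PC	7.5
PC 26:0	PC	6.5
PC 28:0	PC	5.5
PC 28:1	PC	4.5
PC 30:0	PC	8
PC 30:1	PC	7
PC 30:2	PC	6
PC 32:0	PC	5
PC 32:1	PC	4
PC 32:2	PC	7.5
PC 32:3	PC	6.5
PC 33:1	PC	5.5
PC 33:2	PC	4.5
PC 34:0	PC	8
PC 34:1	PC	7
PC 34:2	PC	6
PC 34:3	PC	5
PC 34:4	PC	4
PC 35:1	PC	7.5
PC 35:2	PC	6.5
PC 36:0	PC	5.5
PC 36:1	PC	4.5
PC 36:2	PC	8
PC 36:3	PC	7
PC 36:4	PC	6
PC 36:5	PC	5
PC 36:6	PC	4
PC 37:2	PC	7.5
PC 37:4	PC	6.5
PC 38:0	PC	5.5
PC 38:1	PC	4.5
PC 38:3	PC	8
PC 38:4	PC	7
PC 38:5	PC	6
PC 38:6	PC	5
PC 40:1	PC	4
PC 40:2	PC	7.5
PC 40:4	PC	6.5
PC 40:5	PC	5.5
PC 40:6	PC	4.5
PC 42:0	PC	8
PC 42:1	PC	7
PC 42:2	PC	6
PC 42:4	PC	5
PC 42:5	PC	4
PC 42:6	PC	7.5
PC 44:4	PC	6.5
PC 44:5	PC	5.5
PC 44:6	PC	4.5
PC 40:8	PC	8
LPC 14:0	LPC	5.5
LPC 16:0	LPC	4.5
LPC 16:1	LPC	3.5
LPC 17:0	LPC	2.5
LPC 18:0	LPC	6
LPC 18:1	LPC	5
LPC 18:2	LPC	4
LPC 18:3	LPC	3
LPC 20:0	LPC	6.5
LPC 20:1	LPC	5.5
LPC 20:2	LPC	4.5
LPC 20:3	LPC	3.5
LPC 20:4	LPC	2.5
LPC 22:0	LPC	6
LPC 22:1	LPC	5
LPC 22:4	LPC	4
LPC 22:5	LPC	3
LPC 22:6	LPC	6.5
LPC 24:0	LPC	5.5
LPC 26:0	LPC	4.5
LPC 26:1	LPC	3.5
LPC 28:0	LPC	2.5
SM 18:1;O2/26:0	SM	5.5
SM 18:1;O2/22:2;O	SM	4.5
SM 32:1;O2	SM	3.5
SM 32:2;O2	SM	2.5
SM 34:0;O2	SM	6
SM 34:1;O2	SM	5
SM 34:2;O2	SM	4
SM 36:0;O2	SM	3
SM 36:1;O2	SM	2
SM 36:2;O2	SM	5.5
SM 38:1;O2	SM	4.5
SM 38:2;O2	SM	3.5
SM 40:1;O2	SM	2.5
SM 40:2;O2	SM	6
SM 41:1;O2	SM	5
SM 41:2;O2	SM	4
SM 42:1;O2	SM	3
SM 42:2;O2	SM	2
SM 42:3;O2	SM	5.5
SM 43:1;O2	SM	4.5
PC O-30:0	PC O-	1
PC O-32:0	PC O-	0
PC O-32:1	PC O-	3.5
PC O-34:0	PC O-	2.5
PC O-34:1	PC O-	1.5
PC O-34:2	PC O-	0.5
PC O-34:3	PC O-	-0.5
PC O-36:0	PC O-	3
PC O-36:1	PC O-	2
PC O-36:2	PC O-	1
PC O-36:3	PC O-	0
PC O-36:4;2.0	PC O-	3.5
PC O-36:5	PC O-	2.5
PC O-38:0	PC O-	1.5
PC O-38:5	PC O-	0.5
PC O-38:6	PC O-	-0.5
PC O-40:1	PC O-	3
PC O-40:6	PC O-	2
CAR 2:0	CAR	-1.5
CAR 3:0	CAR	-2.5
CAR 4:0	CAR	1
CAR 6:0	CAR	0
CAR 8:0	CAR	-1
CAR 10:0	CAR	-2
CAR 10:1	CAR	-3
CAR 12:0	CAR	0.5
CAR 12:1	CAR	-0.5
CAR 14:0	CAR	-1.5
CAR 14:1	CAR	-2.5
CAR 16:0	CAR	1
CAR 18:0	CAR	0
CAR 18:1	CAR	-1
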