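hub	partner	day0_3	day3_8	day8_13	day13_29	day29_60
V$SMAD_Q6_01	V$FOX_Q2	+	+	+	+	+
V$SMAD_Q6_01	V$AP1FJ_Q2	+	+	-	+	+
V$SMAD_Q6_01	V$LEF1TCF1_Q4	-	+	+	-	-
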