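hub	partner	day0_3	day3_8	day8_13	day13_29	day29_60
V$AP1_01	V$OCT_C	+	+	-	-	+
V$AP1_01	V$GATA_Q6	+	+	-	+	+
V$AP1_01	V$HNF4_Q6	-	+	-	-	-
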