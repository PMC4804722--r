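hub	partner	day0_3	day3_8	day8_13	day13_29	day29_60
V$HMGIY_Q6	V$OCT_Q6	+	+	+	+	+
V$HMGIY_Q6	V$NFKAPPAB_01	+	+	-	+	+
V$HMGIY_Q6	V$NFKB_Q6_01	+	+	+	+	+
V$HMGIY_Q6	V$NFKB_Q6	+	-	-	-	-
V$HMGIY_Q6	V$ATF3_Q6	+	+	-	-	+
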