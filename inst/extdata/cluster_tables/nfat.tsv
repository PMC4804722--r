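hub	partner	day0_3	day3_8	day8_13	day13_29	day29_60
V$NFAT_Q6	V$PEBP_Q6	+	-	-	-	-
V$NFAT_Q6	V$AP1_C	+	+	+	+	+
V$NFAT_Q6	V$CEBPB_01	+	+	-	+	+
V$NFAT_Q6	V$CREBP1CJUN_01	+	+	+	+	+
V$NFAT_Q6	V$MAF_Q6_01	+	+	+	+	+
V$NFAT_Q6	V$ETS1_B	+	-	-	-	-
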