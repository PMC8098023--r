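# synthetic human-TRB-like germline annotation (1-based, inclusive)
# conserved_pos: start of the conserved Cys (V) / Phe (J) codon
gene	segment	conserved_pos	cdr1_start	cdr1_end	cdr2_start	cdr2_end
TRBV2	V	286	79	114	166	195
TRBV3-1	V	286	79	114	166	195
TRBV4-1	V	286	79	114	166	195
TRBV4-2	V	286	79	114	166	195
TRBV4-3	V	286	79	114	166	195
TRBV5-1	V	286	79	114	166	195
TRBV5-4	V	286	79	114	166	195
TRBV5-5	V	286	79	114	166	195
TRBV5-6	V	286	79	114	166	195
TRBV5-8	V	286	79	114	166	195
TRBV6-1	V	286	79	114	166	195
TRBV6-2	V	286	79	114	166	195
TRBV6-3	V	286	79	114	166	195
TRBV6-4	V	286	79	114	166	195
TRBV6-5	V	286	79	114	166	195
TRBV6-6	V	289	79	114	166	195
TRBV6-8	V	286	79	114	166	195
TRBV6-9	V	286	79	114	166	195
TRBV7-2	V	286	79	114	166	195
TRBV7-3	V	286	79	114	166	195
TRBV7-4	V	286	79	114	166	195
TRBV7-6	V	286	79	114	166	195
TRBV7-7	V	286	79	114	166	195
TRBV7-8	V	286	79	114	166	195
TRBV7-9	V	286	79	114	166	195
TRBV9	V	286	79	114	166	195
TRBV10-1	V	286	79	114	166	195
TRBV10-2	V	286	79	114	166	195
TRBV10-3	V	286	79	114	166	195
TRBV11-1	V	286	79	114	166	195
TRBV11-2	V	286	79	114	166	195
TRBV11-3	V	286	79	114	166	195
TRBV12-3	V	286	79	114	166	195
TRBV12-4	V	286	79	114	166	195
TRBV12-5	V	286	79	114	166	195
TRBV13	V	286	79	114	166	195
TRBV14	V	286	79	114	166	195
TRBV15	V	286	79	114	166	195
TRBV16	V	286	79	114	166	195
TRBV18	V	286	79	114	166	195
TRBV19	V	286	79	114	166	195
TRBJ1-1	J	31	NA	NA	NA	NA
TRBJ1-2	J	31	NA	NA	NA	NA
TRBJ1-3	J	31	NA	NA	NA	NA
TRBJ1-4	J	31	NA	NA	NA	NA
TRBJ1-5	J	31	NA	NA	NA	NA
TRBJ1-6	J	31	NA	NA	NA	NA
TRBJ2-1	J	31	NA	NA	NA	NA
TRBJ2-2	J	31	NA	NA	NA	NA
TRBJ2-3	J	31	NA	NA	NA	NA
TRBJ2-4	J	31	NA	NA	NA	NA
TRBJ2-5	J	31	NA	NA	NA	NA
TRBJ2-6	J	31	NA	NA	NA	NA
TRBJ2-7	J	31	NA	NA	NA	NA
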