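Gprotein_relay	heterotrimeric G protein subunits (alpha, beta, gamma)	GNA11	GNA12	GNA13	GNA14	GNA15	GNAI1	GNAI2	GNAI3	GNAL	GNAO1	GNAQ	GNAS	GNAT1	GNAZ	GNB1	GNB2	GNB3	GNB4	GNB5	GNG2	GNG3	GNG4	GNG5	GNG7	GNG10	GNG11	GNG12
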