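@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:1000
@SQ	SN:chr2	LN:1000
p1	99	chr1	10	60	20M	=	40	50	ACGTACGTACGTACGTACGT	IIIIIIIIIIIIIIIIIIII
p1	147	chr1	40	60	20M	=	10	-50	ACGTACGTACGTACGTACGT	IIIIIIIIIIIIIIIIIIII
u1	0	chr1	300	60	20M	*	0	0	ACGTACGTACGTACGTACGT	IIIIIIIIIIIIIIIIIIII
p2	99	chr2	100	60	20M	=	160	80	ACGTACGTACGTACGTACGT	IIIIIIIIIIIIIIIIIIII
p2	147	chr2	160	60	20M	=	100	-80	ACGTACGTACGTACGTACGT	IIIIIIIIIIIIIIIIIIII
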