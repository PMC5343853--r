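gene	fc_array_LPS	fc_array_PGN	fc_qpcr_LPS	fc_qpcr_PGN
MX	-4.724382	1.739085	-3.62258	4.83517
CD8	-3.8668	-3.8668	-4.85774	-4.85774
TCR	1.470813	-1.21089	2.851373	-1.624026667
CD83	1.3097895	1.4322673	1.979696667	3.03769
GR	-1.189567	1.051587	-1.233847	1.05836
TNNT2	1.9828836	1.2732812	1.979696667	3.03769
G6PC	1.295544	1.738823	3.751023	5.89183
MHCI	1.656065	1.934764	3.62856	6.18487
IL6	2.864684	2.1441178	9.840256667	6.62607
IL1	4.3157287	5.093681	8.908796667	8.970556667
LIPO	1.9686182	7.5816884	1.45541	3.483463333
MHCII	2.8191724	3.3714116	4.03926	4.083143
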