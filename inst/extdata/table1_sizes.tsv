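cluster	n	wss
C1	32	11.81
C2	22	5.43
C3	35	10.88
C4	34	9.13
C5	19	8.52
C6	10	2.13
C7	10	1.59
C8	25	3.14
C9	28	7.15
C10	38	9.93
C11	16	3.44
C12	22	3.4
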