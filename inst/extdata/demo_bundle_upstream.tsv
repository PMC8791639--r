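base	pos1	pos2	pos3	pos4	pos5	pos6	pos7	pos8	pos9	pos10	pos11	pos12
A	0	0.41524920606546295	0.33619725176246579	1.6190128832065362	1.6630595928324519	2.1088272977542837	0	2.5736402127220543	0	0.32323141902364178	0.30459807500979114	0
C	0.42553081958177641	0.35363830796291285	0.2784007527818641	1.6139472917779405	2.0043646852571495	2.482708746066085	2.6091921506936706	0	1.7718379093312369	0.30054474117960112	0.35503525354653986	0.45086614643723738
G	0.37093431630622342	0.28982046107140225	0	1.9037147509641263	2.4036808763038051	0	2.3630359496403894	1.8597936557679564	1.577395967014152	0.3381862887762967	0	0.4972007501394976
T	0.30363933767050683	0	0.30181501502270669	0	0	2.4480588457931463	1.9573256711342555	1.5977666164581514	1.6999586184425075	0	0.49059547423084626	0.48457468311429341
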