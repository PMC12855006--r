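sample_id	class	target
s0001	c1	2.98265022687078
s0002	c1	1.86227579737006
s0003	c1	0.0551106471881671
s0004	c1	1.85332285434346
s0005	c1	1.38433722932734
s0006	c1	2.34135853675885
s0007	c1	3.49145722497795
s0008	c1	2.42480163521804
s0009	c1	3.14247864484066
s0010	c1	3.28563446125045
s0011	c1	0.270153577590721
s0012	c1	1.0129304319216
s0013	c2	-1.86537526460323
s0014	c2	-2.20702048148472
s0015	c2	-3.49639077954829
s0016	c2	-3.04433686275946
s0017	c2	-1.68657675432956
s0018	c2	-1.53598624499507
s0019	c2	-2.78499387736976
s0020	c2	-2.4798899976375
s0021	c2	-2.41209437285882
s0022	c2	-3.45435592961605
s0023	c2	-2.59843618073325
s0024	c2	-0.704049406347282
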