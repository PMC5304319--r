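node_id	tier	fitness
s1_1	supplier	0.34601250903918845
s1_2	supplier	4.3867647264280656
s1_3	supplier	0.25067425030043672
m2_1	manufacturer	1.0040007222060991
m2_2	manufacturer	3.6354267960351065
m2_3	manufacturer	0.73825412918992994
d3_1	distributor	0.36982625347630993
d3_2	distributor	3.5393640832606379
d3_3	distributor	1.9886111354798137
r4_1	retailer	1.1575694895659507
r4_2	retailer	0.95145979036628858
r4_3	retailer	0.98101034058327363
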