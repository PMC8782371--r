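model	pop0	pop1	pop2	loglik10	n_params	aic_printed	delta_printed
M1	G	I	P	-127172.5	11	585672.9	29217.3
M2	I	P	G	-127229.0	11	585933.3	29477.7
M3	P	G	I	-127286.5	11	586198.1	29742.5
M4	G	P	I	-127281.5	11	586174.7	29719.1
M5	I	G	P	-127261.8	11	586084.3	29628.7
M6	P	I	G	-127153.6	11	585585.7	29130.1
M7	G	I	P	-126330.1	11	581793.6	25338.0
M8	I	P	G	-127334.0	11	586416.5	29960.9
M9	P	G	I	-127219.8	11	585890.9	29435.3
M10	G	P	I	-127576.1	11	587531.8	31076.2
M11	I	G	P	-127356.7	11	586521.2	30065.6
M12	P	I	G	-127250.8	11	586033.5	29577.9
M13	G	I	P	-120975.1	15	557141.0	685.4
M14	I	P	G	-120873.1	15	556671.3	215.7
M15	P	G	I	-120944.8	15	557001.5	545.9
M16	G	P	I	-120967.7	15	557106.9	651.3
M17	I	G	P	-120983.8	15	557181.0	725.4
M18	P	I	G	-120858.9	15	556605.7	150.1
M19	G	I	P	-120890.9	15	556753.1	297.5
M20	I	P	G	-120992.7	15	557221.8	766.2
M21	P	G	I	-120972.1	15	557127.3	671.7
M22	G	P	I	-120826.3	15	556455.6	0.0
M23	I	G	P	-121018.4	15	557340.6	885.0
M24	P	I	G	-121035.5	15	557418.9	963.2
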