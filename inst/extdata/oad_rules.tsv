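rule_id	bond_site	hydrogen_delta	oxygen_delta	water_loss	rel_intensity	diagnostic	applicability
OAD01	-1	-1	1	FALSE	0.05	FALSE	all
OAD02	-1	0	1	TRUE	0.03	FALSE	all
OAD03	-1	0	1	FALSE	0.10	TRUE	all
OAD04	-1	1	1	FALSE	0.04	FALSE	all
OAD05	-1	-1	0	FALSE	0.02	FALSE	all
OAD06	-1	0	0	FALSE	0.03	FALSE	all
OAD07	-1	1	0	FALSE	0.02	FALSE	all
OAD08	0	-1	1	FALSE	0.03	FALSE	all
OAD09	0	0	1	FALSE	0.05	FALSE	all
OAD10	0	1	1	FALSE	0.05	FALSE	all
OAD11	0	0	1	TRUE	0.02	FALSE	all
OAD12	0	-1	0	FALSE	0.02	FALSE	all
OAD13	0	0	0	FALSE	0.03	FALSE	all
OAD14	0	1	0	FALSE	0.02	FALSE	all
OAD15	1	-1	0	FALSE	0.04	FALSE	all
OAD16	1	0	0	FALSE	0.10	TRUE	all
OAD17	1	1	0	FALSE	0.04	FALSE	all
OAD18	1	0	1	FALSE	0.02	FALSE	all
OAD19	1	0	1	TRUE	0.02	FALSE	all
OAD20	1	1	1	FALSE	0.02	FALSE	all
VE01	-1	0	1	FALSE	0.05	FALSE	vinyl_ether
VE02	-1	-1	1	FALSE	0.03	FALSE	vinyl_ether
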