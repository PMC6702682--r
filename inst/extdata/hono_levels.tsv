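# Published 21 lowest vibrational eigenvalues (cm-1, relative to the ground
# state) of 6D HONO in the cis-trans isomerization region, for four surface
# parametrizations: unmodified PM7, reparametrized fits on 53 and 1084
# reference points, and the analytical coupled-cluster-quality reference.
pm7	srp53	srp1084	analytical
0.0	0.0	0.0	0.0
593.6	163.0	88.5	94.1
794.3	604.7	597.1	600.8
1070.6	693.2	703.9	710.7
1151.5	706.9	822.3	795.9
1186.3	888.9	917.9	944.1
1365.9	1134.3	1012.5	1055.4
1403.1	1204.8	1189.7	1188.1
1641.3	1221.6	1234.7	1264.9
1659.6	1263.0	1317.9	1306.6
1751.1	1308.9	1363.5	1312.8
1773.1	1361.6	1417.2	1385.3
1811.5	1395.7	1451.1	1404.8
1869.9	1424.9	1530.5	1547.9
1968.7	1426.3	1607.7	1574.9
2011.4	1612.4	1633.9	1640.9
2060.3	1656.9	1690.9	1689.9
2118.1	1698.3	1743.0	1726.0
2136.5	1748.6	1778.7	1762.4
2226.5	1842.0	1785.8	1779.7
2253.3	1853.0	1807.3	1829.0
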