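# MM-GBSA binding-energy components for ZBTB BTB-domain dimers (kcal/mol),
# as printed in the reference analyses of 500-ns dimer trajectories.
# dg_expected (heterodimers) is the printed mean of the parent homodimer
# totals; window_ns is the equilibrated interval used for averaging.
dimer	kind	window_ns	dg_total	dg_expected	de_int	de_ele	dg_sol_pb	dg_sol_sa	de_vdw	n_residues	dg_per_aa	avg_bsa	pct_interface	avg_salt_bridges
PATZ1	homodimer	300-500	-529.1	NA	-353.9	-418.0	437.1	0.0	-194.3	290	-1.8	1864	40.7	1.7
BCL6	homodimer	1-500	-401.6	NA	-237.5	-278.7	330.6	-25.4	-190.5	250	-1.6	1899	34.8	1.2
MIZ1	homodimer	100-500	-384.1	NA	-282.8	-170.0	235.9	-18.8	-148.4	234	-1.6	1471	37.2	0.3
LRF	homodimer	280-500	-520.3	NA	-380.0	-322.8	399.6	-22.3	-194.7	244	-2.1	1752	36.9	0.8
PATZ2	homodimer	100-500	-485.4	NA	-335.5	-247.8	254.5	43.3	-200.0	258	-1.9	2037	38.0	0.3
PATZ1-PATZ2	heterodimer	350-500	-529.5	-507.3	-340.0	-471.0	535.4	-30.4	-223.4	274	-1.9	2348	40.1	2.5
PATZ1-BCL6	heterodimer	60-500	-470.9	-465.4	-306.6	-461.6	531.0	-27.3	-206.4	270	-1.7	2054	37.8	1.3
MIZ1-BCL6	heterodimer	180-500	-397.6	-392.9	-272.3	-152.8	202.7	-19.6	-155.7	242	-1.6	1548	33.1	0.6
LRF-ThPOK	heterodimer	350-500	-471.3	NA	-348.6	-249.3	316.4	-21.0	-168.8	259	-1.8	1706	34.7	1.5
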