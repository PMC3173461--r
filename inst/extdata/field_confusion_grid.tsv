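kernel	k	n_replete_pred_deficient	n_deficient_pred_replete	n_replete_pred_replete	n_deficient_pred_deficient	percent_correct
poly1	25	5	7	10	8	60.0
poly2	25	3	9	12	6	60.0
poly3	25	2	7	13	8	70.0
rbf	25	2	7	13	8	70.0
poly1	50	6	2	9	13	73.3
poly2	50	0	3	15	12	90.0
poly3	50	0	4	15	11	86.7
rbf	50	0	4	15	11	86.7
poly1	100	7	0	8	15	76.7
poly2	100	0	3	15	12	90.0
poly3	100	0	3	15	12	90.0
rbf	100	2	3	13	12	83.3
poly1	200	0	0	15	15	100.0
poly2	200	0	0	15	15	100.0
poly3	200	0	0	15	15	100.0
rbf	200	0	0	15	15	100.0
poly1	250	2	0	13	15	93.3
poly2	250	1	0	14	15	96.7
poly3	250	1	0	14	15	96.7
rbf	250	1	0	14	15	96.7
poly1	1000	3	0	12	15	90.0
poly2	1000	2	0	13	15	93.3
poly3	1000	2	0	13	15	93.3
rbf	1000	2	0	13	15	93.3
poly1	8663	4	0	11	15	86.7
poly2	8663	2	1	13	14	90.0
poly3	8663	2	2	13	13	86.7
rbf	8663	2	2	13	13	86.7
poly1	28946	2	2	13	13	86.7
poly2	28946	3	1	12	14	86.7
poly3	28946	5	2	10	13	76.7
rbf	28946	5	2	10	13	76.7
poly1	42094	2	9	13	6	63.3
poly2	42094	0	15	15	0	50.0
poly3	42094	0	15	15	0	50.0
rbf	42094	0	14	15	1	53.3
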