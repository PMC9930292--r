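patient_id	amenorrhea	menarche_age	onset_age	fsh	lh	e2	karyotype
POI-1	SA	15	26	73.35	41.08	5.60	46,XX
POI-2	SA	15	15	109.90	57.32	<5.00	46,XX
POI-3	SA	12	31	39.91	36.25	80.60	46,XX
POI-4	SA	13	17	101.80	40.84	<11.80	46,XX
POI-5	PA	19	19	43.56	40.01	16.40	46,XX
POI-6	SA	15	28	69.89	32.20	73.21	46,XX
POI-7	SA	11	20	74.41	30.80	2.12	46,XX
POI-8	SA	12	25	81.03	55.21	11.40	46,XX
POI-9	SA	15	20	46.08	32.33	80.67	46,XX
POI-10	SA	14	24	62.40	11.80	<20.00	46,XX
POI-11	SA	15	ND	54.61	66.21	13.50	46,XX
POI-12	SA	13	28	40.59	27.66	35.71	46,XX
POI-13	SA	13	23	18.11	6.22	11.43	46,XX
POI-14	SA	14	16	71.56	45.34	42.70	46,XX
POI-15	PA	16	23	59.93	18.96	7.20	46,XX
POI-16	SA	13	26	65.71	42.52	18.80	46,XX
POI-17	PA	18	18	131.15	8.19	<5.00	46,XX
POI-18	SA	12	18	77.54	36.67	<5.00	46,XX
POI-19	SA	14	14	24.89	8.18	51.20	46,XX
POI-20	SA	13	20	77.32	38.22	<5.00	46,XX
POI-21	SA	12	27	92.73	56.51	52.20	46,XX
POI-22	PA	16	20	ND	ND	ND	46,XX
POI-23	SA	15	17	107.78	29.87	24.08	46,XX
POI-24	SA	14	30	33.59	17.86	103.77	46,XX
POI-25	PA	17	17	36.98	10.56	5.30	46,XX
POI-26	SA	14	30	76.15	57.85	12.90	46,XX
POI-27	SA	15	31	134.50	64.46	32.43	46,XX
POI-28	SA	14	30	90.65	59.31	<5.00	46,XX
POI-29	SA	12	32	71.96	48.51	21.53	46,XX
POI-30	SA	13	23	113.67	31.46	5.79	46,XX
POI-31	SA	12	27	ND	ND	ND	46,XX
POI-32	SA	12	26	ND	ND	ND	46,XX
POI-33	SA	13	24	ND	ND	ND	46,XX
POI-34	SA	14	35	ND	ND	ND	46,XX
POI-35	SA	15	ND	ND	ND	ND	46,XX
POI-36	SA	14	ND	ND	ND	ND	46,XX
POI-37	SA	13	24	125.53	57.32	<5.00	46,XX
POI-38	PA	16	24	59.18	28.09	40.32	46,XX
POI-39	SA	ND	ND	49.22	21.95	17.64	46,XX
POI-40	SA	13	37	58.16	18.42	20.24	46,XX
POI-41	SA	14	14	60.82	9.75	<20.00	46,XX
POI-42	SA	14	20	121.53	110.57	20.53	46,XX
POI-43	SA	14	31	60.13	37.06	5.20	46,XX
POI-44	PA	16	30	36.21	40.54	88.54	46,XX
POI-45	SA	13	25	60.49	39.16	48.68	46,XX
POI-46	SA	10	26	77.32	44.05	14.32	46,XX
POI-47	PA	17	20	76.23	22.59	39.64	46,XX
POI-48	SA	ND	ND	ND	ND	ND	46,XX
POI-49	SA	13	35	91.58	37.34	10.35	46,XX
POI-50	PA	16	16	46.34	9.54	<5.00	46,XX
POI-51	PA	17	17	ND	ND	ND	46,XX
POI-52	SA	14	25	59.32	17.78	12.32	46,XX
POI-53	PA	19	19	ND	ND	ND	46,XX
POI-54	PA	17	17	83.46	39.56	9.20	46,XX
POI-55	SA	13	19	79.35	44.95	3.99	46,XX
POI-56	PA	16	16	75.53	24.05	5.50	46,XX
POI-57	SA	12	20	91.66	41.98	14.20	46,XX
POI-58	SA	14	31	66.95	37.22	24.43	46,XX
POI-59	SA	15	37	55.49	40.04	59.33	46,XX
POI-60	SA	13	ND	40.65	20.09	<10.00	46,XX
POI-61	SA	15	ND	96.01	60.93	71.34	46,XX
POI-62	PA	18	18	51.89	33.83	26.55	46,XX
POI-63	PA	19	26	117.83	41.01	7.83	46,XX
POI-64	SA	13	22	104.93	33.36	59.22	46,XX
POI-65	SA	14	25	107.22	57.03	18.35	46,XX
POI-66	SA	15	28	65.96	22.86	35.15	46,XX
POI-67	PA	16	16	54.97	16.16	19.32	46,XX
POI-68	SA	15	18	124.66	47.81	16.21	46,XX
POI-69	PA	16	26	91.68	58.68	<5.00	46,XX
POI-70	SA	15	21	98.26	36.23	23.13	46,XX
POI-71	SA	15	27	141.95	57.14	<5.00	46,XX
POI-72	SA	15	ND	41.11	24.45	<5.00	46,XX
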