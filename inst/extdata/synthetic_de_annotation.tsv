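gene	chromosome	cytoband	direction
SYNGENE001	HSA1	q15.2	up
SYNGENE002	HSA1	p13.3	up
SYNGENE003	HSA1	p22.3	up
SYNGENE004	HSA1	p27.1	up
SYNGENE005	HSA1	p13.2	up
SYNGENE006	HSA1	q13.1	up
SYNGENE007	HSA1	p28.2	up
SYNGENE008	HSA1	p29.1	up
SYNGENE009	HSA1	p31.3	down
SYNGENE010	HSA1	p29.3	down
SYNGENE011	HSA1	q12.1	down
SYNGENE012	HSA1	p28.1	down
SYNGENE013	HSA1	q24.1	down
SYNGENE014	HSA1	p29.2	down
SYNGENE015	HSA1	p14.3	down
SYNGENE016	HSA1	p22.1	down
SYNGENE017	HSA1	p29.1	down
SYNGENE018	HSA3	p26.3	up
SYNGENE019	HSA3	q35.2	up
SYNGENE020	HSA3	q29.2	up
SYNGENE021	HSA3	q20.1	up
SYNGENE022	HSA3	p33.1	up
SYNGENE023	HSA3	p29.2	up
SYNGENE024	HSA3	q21.3	up
SYNGENE025	HSA3	q20.3	down
SYNGENE026	HSA3	p14.3	down
SYNGENE027	HSA3	q16.2	down
SYNGENE028	HSA3	p26.2	down
SYNGENE029	HSA3	p32.1	down
SYNGENE030	HSA3	q21.3	down
SYNGENE031	HSA3	q30.2	down
SYNGENE032	HSA3	q13.1	down
SYNGENE033	HSA7	q26.3	up
SYNGENE034	HSA7	p12.3	up
SYNGENE035	HSA7	q31.3	up
SYNGENE036	HSA7	q20.3	up
SYNGENE037	HSA7	q32.2	up
SYNGENE038	HSA7	p25.2	up
SYNGENE039	HSA7	p30.1	up
SYNGENE040	HSA7	q12.1	up
SYNGENE041	HSA7	q15.3	down
SYNGENE042	HSA7	p23.2	down
SYNGENE043	HSA7	q13.1	down
SYNGENE044	HSA7	q23.3	down
SYNGENE045	HSA7	q15.2	down
SYNGENE046	HSA11	q33.2	up
SYNGENE047	HSA11	q32.2	up
SYNGENE048	HSA11	p15.1	up
SYNGENE049	HSA11	p15.1	up
SYNGENE050	HSA11	p11.2	up
SYNGENE051	HSA11	p19.2	up
SYNGENE052	HSA11	p15.2	down
SYNGENE053	HSA11	q30.3	down
SYNGENE054	HSA11	q15.3	down
SYNGENE055	HSA11	p25.3	down
SYNGENE056	HSA11	q23.2	down
SYNGENE057	HSA11	q14.2	down
SYNGENE058	HSA11	q12.1	down
SYNGENE059	HSA12	p17.2	up
SYNGENE060	HSA12	p14.2	up
SYNGENE061	HSA12	p14.1	up
SYNGENE062	HSA12	p28.1	up
SYNGENE063	HSA12	q30.1	up
SYNGENE064	HSA12	p17.3	up
SYNGENE065	HSA12	q15.3	up
SYNGENE066	HSA12	q22.3	up
SYNGENE067	HSA12	q26.1	down
SYNGENE068	HSA12	p26.2	down
SYNGENE069	HSA12	q26.2	down
SYNGENE070	HSA12	p15.1	down
SYNGENE071	HSA12	q34.2	down
SYNGENE072	HSA12	q33.1	down
SYNGENE073	HSA12	p17.3	down
SYNGENE074	HSA12	q15.3	down
SYNGENE075	HSA12	p35.3	down
SYNGENE076	HSA17	q31.1	up
SYNGENE077	HSA17	q27.2	up
SYNGENE078	HSA17	p22.1	up
SYNGENE079	HSA17	q31.1	up
SYNGENE080	HSA17	p36.1	up
SYNGENE081	HSA17	q34.1	up
SYNGENE082	HSA17	p27.2	up
SYNGENE083	HSA17	q34.1	down
SYNGENE084	HSA17	p36.2	down
SYNGENE085	HSA17	q19.1	down
SYNGENE086	HSA17	q25.3	down
SYNGENE087	HSA17	q22.1	down
SYNGENE088	HSA17	p14.1	down
SYNGENE089	HSA17	q17.2	down
SYNGENE090	HSA17	p26.3	down
SYNGENE091	HSAX	p26.3	up
SYNGENE092	HSAX	q36.3	up
SYNGENE093	HSAX	p32.1	up
SYNGENE094	HSAX	q36.3	up
SYNGENE095	HSAX	p26.1	up
SYNGENE096	HSAX	q36.3	up
SYNGENE097	HSAX	q13.3	down
SYNGENE098	HSAX	q25.2	down
SYNGENE099	HSAX	p34.1	down
SYNGENE100	HSAX	p15.1	down
SYNGENE101	HSAX	p29.2	down
SYNGENE102	HSAX	p30.3	down
SYNGENE103	HSAX	q32.2	down
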