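# Cohort fixture: per-cycle transfer outcome records (see docs).
#cycle_id	embryos_transferred	sacs	clinical_pregnancy	live_birth	early_miscarriage
SET_001	1	1	1	1	0
SET_002	1	1	1	1	0
SET_003	1	1	1	1	0
SET_004	1	1	1	1	0
SET_005	1	1	1	1	0
SET_006	1	1	1	1	0
SET_007	1	1	1	1	0
SET_008	1	1	1	1	0
SET_009	1	1	1	1	0
SET_010	1	1	1	1	0
SET_011	1	1	1	1	0
SET_012	1	1	1	1	0
SET_013	1	1	1	1	0
SET_014	1	1	1	1	0
SET_015	1	1	1	1	0
SET_016	1	1	1	1	0
SET_017	1	1	1	1	0
SET_018	1	1	1	1	0
SET_019	1	1	1	1	0
SET_020	1	1	1	1	0
SET_021	1	1	1	1	0
SET_022	1	1	1	1	0
SET_023	1	1	1	1	0
SET_024	1	1	1	1	0
SET_025	1	1	1	1	0
SET_026	1	1	1	1	0
SET_027	1	1	1	1	0
SET_028	1	1	1	1	0
SET_029	1	1	1	1	0
SET_030	1	1	1	1	0
SET_031	1	1	1	1	0
SET_032	1	1	1	1	0
SET_033	1	1	1	1	0
SET_034	1	1	1	1	0
SET_035	1	1	1	1	0
SET_036	1	1	1	1	0
SET_037	1	1	1	1	0
SET_038	1	1	1	1	0
SET_039	1	1	1	1	0
SET_040	1	1	1	1	0
SET_041	1	1	1	1	0
SET_042	1	1	1	1	0
SET_043	1	1	1	1	0
SET_044	1	1	1	1	0
SET_045	1	1	1	1	0
SET_046	1	1	1	1	0
SET_047	1	1	1	1	0
SET_048	1	1	1	1	0
SET_049	1	1	1	0	1
SET_050	1	1	1	0	1
SET_051	1	0	0	0	0
SET_052	1	0	0	0	0
SET_053	1	0	0	0	0
SET_054	1	0	0	0	0
SET_055	1	0	0	0	0
SET_056	1	0	0	0	0
SET_057	1	0	0	0	0
SET_058	1	0	0	0	0
SET_059	1	0	0	0	0
SET_060	1	0	0	0	0
SET_061	1	0	0	0	0
SET_062	1	0	0	0	0
SET_063	1	0	0	0	0
SET_064	1	0	0	0	0
SET_065	1	0	0	0	0
SET_066	1	0	0	0	0
SET_067	1	0	0	0	0
SET_068	1	0	0	0	0
SET_069	1	0	0	0	0
SET_070	1	0	0	0	0
SET_071	1	0	0	0	0
SET_072	1	0	0	0	0
SET_073	1	0	0	0	0
SET_074	1	0	0	0	0
SET_075	1	0	0	0	0
SET_076	1	0	0	0	0
SET_077	1	0	0	0	0
SET_078	1	0	0	0	0
SET_079	1	0	0	0	0
SET_080	1	0	0	0	0
SET_081	1	0	0	0	0
SET_082	1	0	0	0	0
SET_083	1	0	0	0	0
SET_084	1	0	0	0	0
SET_085	1	0	0	0	0
SET_086	1	0	0	0	0
SET_087	1	0	0	0	0
SET_088	1	0	0	0	0
SET_089	1	0	0	0	0
SET_090	1	0	0	0	0
SET_091	1	0	0	0	0
SET_092	1	0	0	0	0
SET_093	1	0	0	0	0
SET_094	1	0	0	0	0
SET_095	1	0	0	0	0
SET_096	1	0	0	0	0
SET_097	1	0	0	0	0
SET_098	1	0	0	0	0
SET_099	1	0	0	0	0
SET_100	1	0	0	0	0
SET_101	1	0	0	0	0
SET_102	1	0	0	0	0
SET_103	1	0	0	0	0
SET_104	1	0	0	0	0
SET_105	1	0	0	0	0
SET_106	1	0	0	0	0
SET_107	1	0	0	0	0
SET_108	1	0	0	0	0
SET_109	1	0	0	0	0
SET_110	1	0	0	0	0
SET_111	1	0	0	0	0
SET_112	1	0	0	0	0
SET_113	1	0	0	0	0
DET_001	2	2	1	1	0
DET_002	2	2	1	1	0
DET_003	2	2	1	1	0
DET_004	2	2	1	1	0
DET_005	2	2	1	1	0
DET_006	2	2	1	1	0
DET_007	2	2	1	1	0
DET_008	2	2	1	1	0
DET_009	2	2	1	1	0
DET_010	2	2	1	1	0
DET_011	2	2	1	1	0
DET_012	2	2	1	1	0
DET_013	2	2	1	1	0
DET_014	2	2	1	1	0
DET_015	2	2	1	1	0
DET_016	2	2	1	1	0
DET_017	2	2	1	1	0
DET_018	2	1	1	1	0
DET_019	2	1	1	1	0
DET_020	2	1	1	1	0
DET_021	2	1	1	1	0
DET_022	2	1	1	1	0
DET_023	2	1	1	1	0
DET_024	2	1	1	1	0
DET_025	2	1	1	1	0
DET_026	2	1	1	1	0
DET_027	2	1	1	1	0
DET_028	2	1	1	1	0
DET_029	2	1	1	1	0
DET_030	2	1	1	1	0
DET_031	2	1	1	1	0
DET_032	2	1	1	1	0
DET_033	2	1	1	0	0
DET_034	2	0	0	0	0
DET_035	2	0	0	0	0
DET_036	2	0	0	0	0
DET_037	2	0	0	0	0
DET_038	2	0	0	0	0
DET_039	2	0	0	0	0
DET_040	2	0	0	0	0
DET_041	2	0	0	0	0
DET_042	2	0	0	0	0
DET_043	2	0	0	0	0
DET_044	2	0	0	0	0
DET_045	2	0	0	0	0
DET_046	2	0	0	0	0
DET_047	2	0	0	0	0
DET_048	2	0	0	0	0
DET_049	2	0	0	0	0
DET_050	2	0	0	0	0
DET_051	2	0	0	0	0
DET_052	2	0	0	0	0
DET_053	2	0	0	0	0
DET_054	2	0	0	0	0
DET_055	2	0	0	0	0
DET_056	2	0	0	0	0
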