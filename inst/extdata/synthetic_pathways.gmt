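SYN_AIS_PEAK	synthetic trajectory module: AIS_peak	m_AIS_peak_01	m_AIS_peak_02	m_AIS_peak_03	m_AIS_peak_04	m_AIS_peak_05	m_AIS_peak_06	m_AIS_peak_07	m_AIS_peak_08	m_AIS_peak_09	m_AIS_peak_10	m_AIS_peak_11	m_AIS_peak_12	m_AIS_peak_13	m_AIS_peak_14	m_AIS_peak_15	m_AIS_peak_16	m_AIS_peak_17	m_AIS_peak_18	m_AIS_peak_19	m_AIS_peak_20
SYN_MIA_PEAK	synthetic trajectory module: MIA_peak	m_MIA_peak_01	m_MIA_peak_02	m_MIA_peak_03	m_MIA_peak_04	m_MIA_peak_05	m_MIA_peak_06	m_MIA_peak_07	m_MIA_peak_08	m_MIA_peak_09	m_MIA_peak_10	m_MIA_peak_11	m_MIA_peak_12	m_MIA_peak_13	m_MIA_peak_14	m_MIA_peak_15	m_MIA_peak_16	m_MIA_peak_17	m_MIA_peak_18	m_MIA_peak_19	m_MIA_peak_20
SYN_UP	synthetic trajectory module: up	m_up_01	m_up_02	m_up_03	m_up_04	m_up_05	m_up_06	m_up_07	m_up_08	m_up_09	m_up_10	m_up_11	m_up_12	m_up_13	m_up_14	m_up_15	m_up_16	m_up_17	m_up_18	m_up_19	m_up_20
SYN_DOWN	synthetic trajectory module: down	m_down_01	m_down_02	m_down_03	m_down_04	m_down_05	m_down_06	m_down_07	m_down_08	m_down_09	m_down_10	m_down_11	m_down_12	m_down_13	m_down_14	m_down_15	m_down_16	m_down_17	m_down_18	m_down_19	m_down_20
SYN_SIG1	synthetic subtype S1 signature module	m_sig1_01	m_sig1_02	m_sig1_03	m_sig1_04	m_sig1_05	m_sig1_06	m_sig1_07	m_sig1_08	m_sig1_09	m_sig1_10	m_sig1_11	m_sig1_12	m_sig1_13	m_sig1_14	m_sig1_15
SYN_SIG2	synthetic subtype S2 signature module	m_sig2_01	m_sig2_02	m_sig2_03	m_sig2_04	m_sig2_05	m_sig2_06	m_sig2_07	m_sig2_08	m_sig2_09	m_sig2_10	m_sig2_11	m_sig2_12	m_sig2_13	m_sig2_14	m_sig2_15
SYN_BILE	bile acid module (elevated in the last subtype)	cholic acid	chenodeoxycholic acid	deoxycholic acid	glycocholic acid	glycochenodeoxycholic acid	glycodeoxycholic acid	taurocholic acid	taurochenodeoxycholic acid	taurodeoxycholic acid
SYN_BG_A	background module A (no planted effect)	m_bg_001	m_bg_002	m_bg_003	m_bg_004	m_bg_005	m_bg_006	m_bg_007	m_bg_008	m_bg_009	m_bg_010	m_bg_011	m_bg_012	m_bg_013	m_bg_014	m_bg_015	m_bg_016	m_bg_017	m_bg_018	m_bg_019	m_bg_020
SYN_BG_B	background module B (no planted effect)	m_bg_021	m_bg_022	m_bg_023	m_bg_024	m_bg_025	m_bg_026	m_bg_027	m_bg_028	m_bg_029	m_bg_030	m_bg_031	m_bg_032	m_bg_033	m_bg_034	m_bg_035	m_bg_036	m_bg_037	m_bg_038	m_bg_039
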