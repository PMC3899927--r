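gene_id	ctrl_01	ctrl_02	ctrl_03	ctrl_04	ctrl_05	ctrl_06	ctrl_07	ctrl_08	ctrl_09	ctrl_10	test_01	test_02	test_03	test_04	test_05	test_06	test_07	test_08	test_09	test_10
MACF1	11.1435	11.286	11.2249	11.1258	11.0325	11.1108	11.3377	11.1821	11.0675	11.2381	11.0375	11.0792	10.9673	11.0367	11.1054	10.9261	11.0433	10.9484	10.9412	10.8385
TREM2	6.2856	6.4891	5.7799	6.1081	6.3129	6.3208	6.4826	6.2005	5.8922	6.2148	11.6792	8.1128	6.6253	6.8334	7.6417	7.5133	5.9633	7.4631	6.5666	7.602
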