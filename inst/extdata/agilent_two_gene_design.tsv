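sample_id	group
ctrl_01	control
ctrl_02	control
ctrl_03	control
ctrl_04	control
ctrl_05	control
ctrl_06	control
ctrl_07	control
ctrl_08	control
ctrl_09	control
ctrl_10	control
test_01	test
test_02	test
test_03	test
test_04	test
test_05	test
test_06	test
test_07	test
test_08	test
test_09	test
test_10	test
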