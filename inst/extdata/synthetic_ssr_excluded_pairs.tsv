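marker1	marker2
synmk_c4_01	synmk_c4_02
synmk_c4_01	synmk_c4_03
synmk_c4_01	synmk_c4_04
synmk_c4_01	synmk_c4_05
synmk_c4_01	synmk_c4_06
synmk_c4_01	synmk_c4_07
synmk_c4_02	synmk_c4_03
synmk_c4_02	synmk_c4_04
synmk_c4_02	synmk_c4_05
synmk_c4_02	synmk_c4_06
synmk_c4_02	synmk_c4_07
synmk_c4_03	synmk_c4_04
synmk_c4_03	synmk_c4_05
synmk_c4_03	synmk_c4_06
synmk_c4_03	synmk_c4_07
synmk_c4_04	synmk_c4_05
synmk_c4_04	synmk_c4_06
synmk_c4_04	synmk_c4_07
synmk_c4_05	synmk_c4_06
synmk_c4_05	synmk_c4_07
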