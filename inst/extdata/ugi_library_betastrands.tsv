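library	clone	sequence	functional
L1	U10	PTRSIVK	FALSE
L1	U12	KSNKSLP	FALSE
L2	L2_01	QESILML	TRUE
L2	L2_02	QEAMLML	TRUE
L3	L3_01	QEALLML	TRUE
L3	L3_02	QESTLML	TRUE
L3	L3_03	QESVLML	TRUE
L3	L3_04	QETCLML	TRUE
L3	L3_05	QESWLML	TRUE
L3	L3_06	QEAPLML	TRUE
L3	L3_07	QETVLML	TRUE
L3	L3_08	QEVTLML	TRUE
L3	L3_09	QETMLML	TRUE
L3	L3_10	QETILML	TRUE
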