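sample	assays	germline	loh	somatic
AA1844T	A + E + T		subclonal	Q393* (E:12%, T:20%)
AA1968T	A + E + T			
AA2273T	A + E + T			K453* (E:48%, T:51%)
AA2463T	A + E + T	Y44*	chr3	
AA2476T	A + E + T		15 Mb	I71fs (E:14%, T:20%)
AA2528T	A + E + T			
AA2253T	A + E + T		0.34 Mb	
AA2489T	A + T	NA	54 Mb	
AA2617T	A + T	NA		A95fs (39%)
AA2830T	T	NA	NA	
AA2627T	T	NA	NA	Q684* (50%)
AA2819T	T	NA	NA	
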