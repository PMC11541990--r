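label	numerator	denominator	description
canonical_hc_mbl	173	332	individuals with >=1 canonical CLL-associated mCA among HC-MBL
canonical_lc_mbl	8	728	individuals with >=1 canonical CLL-associated mCA among LC-MBL
canonical_no_mbl	4	2971	individuals with >=1 canonical CLL-associated mCA among no-MBL
canonical_tn_no_mbl	2967	2971	no-MBL individuals without a canonical mCA (specificity numerator)
loy_males	325	2170	males with mosaic loss of Y
lox_females	41	2462	females with mosaic loss of X
driver_screen_tp	190	332	HC-MBL individuals with >=1 CLL-driver mCA (screen sensitivity)
driver_screen_tn	3645	3699	LC-MBL/no-MBL individuals without a CLL-driver mCA (screen specificity)
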