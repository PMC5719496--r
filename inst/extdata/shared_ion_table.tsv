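mz	lipid_id	isotope_flag	category	mz_alias
635.6	unknown	FALSE	EQ	NA
645.6	unknown	FALSE	IMS_LT	NA
681.5	unknown	FALSE	IMS_LLT	NA
697.4	Phospholipid	FALSE	IMS_GT	697.35
698.4	unknown	FALSE	IMS_LLT	NA
712.4	Phospholipid	FALSE	EQ	712.3
713.6	Phospholipid	FALSE	IMS_GT	713.75
714.6	NA	TRUE	IMS_GGT	NA
728.3	Phospholipid	FALSE	IMS_GT	728.2
729.3	Phospholipid	FALSE	IMS_GGT	729.22
834.7	PS(40:6)	FALSE	IMS_GGT	834.67
883.7	PI(38:5)	FALSE	IMS_LT	NA
884.7	NA	TRUE	EQ	NA
885.7	PI(38:4)	FALSE	EQ	885.62
886.7	PI(38:3)	FALSE	IMS_LT	886.64
887.7	Phospholipid	FALSE	IMS_LT	NA
888.7	ST(24:1)	FALSE	IMS_LLT	888.65
889.7	NA	TRUE	IMS_LLT	NA
890.7	ST(24:0)	FALSE	IMS_LLT	890.66
905.4	NA	TRUE	IMS_GT	NA
906.4	ST(24:0)(OH)	FALSE	IMS_LLT	NA
907.4	Phospholipid	FALSE	IMS_LT	NA
912.8	PI(40:4)	FALSE	IMS_LT	NA
913.7	NA	TRUE	EQ	NA
923.3	unknown	FALSE	IMS_GT	NA
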