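kind	acc_a	acc_b	species_a	species_b	distance
conspecific_merge	NA	FJ170791	Mystus vittatus	Mystus horai	NA
conspecific_merge	NA	DQ508069	Bagarius bagarius	Bagarius yarrelli	NA
deep_conspecific_divergence	NA	HQ654701	Clarias batrachus	Clarias batrachus	NA
deep_conspecific_divergence	NA	EU490873	Amblyceps apangi	Amblyceps apangi	NA
deep_conspecific_divergence	NA	DQ508066	Amblyceps apangi	Amblyceps apangi	NA
deep_conspecific_divergence	NA	DQ514362	Glyptothorax telchitta	Glyptothorax telchitta	NA
deep_conspecific_divergence	NA	DQ508077	Glyptothorax trilineatus	Glyptothorax trilineatus	NA
deep_conspecific_divergence	NA	DQ508074	Erethistes pusillus	Erethistes pusillus	NA
deep_conspecific_divergence	NA	DQ508079	Erethistes pusillus	Erethistes pusillus	NA
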