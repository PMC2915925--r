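quantity	count
union_any_study	372
validated_regulators_all_studies	211
prior_regulators	184
prior_recovered_by_this_study	143
novel_validated_this_study	26
fatty_acid_study_regulators	175
fatty_acid_only_this_study	8
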