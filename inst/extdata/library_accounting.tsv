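quantity	count
strains_arrayed	4827
duplicate_positions	52
failed_construction	256
wrong_mating_type_or_diploid	457
strains_with_data	4049
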