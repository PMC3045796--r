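key	value
officials_with_abstracts	73
aliases_with_abstracts	256
total_abstracts_with_abstracts	13355
unique_ids_with_abstracts	11022
officials_meeting_requirements	68
aliases_meeting_requirements	223
total_abstracts_meeting_requirements	12088
unique_ids_meeting_requirements	10312
officials_final	68
synonym_aliases_final	165
total_abstracts_final	9005
unique_ids_final	7523
unique_ids_officials_only	2099
ambiguous_aliases	58
genes_with_ambiguous_aliases	36
synonym_collections_mentioning_official	67
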