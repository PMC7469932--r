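# Provenance of the capuli S-RNase allele catalogue.
# intron1_described: allele already resolvable by Intron-I length markers.
# full_length_sequenced: full-length S-RNase sequence obtained.
# accession_panel: detected by CAPS among the 15 reference accessions.
# orchard_panel: detected by CAPS among the 7 orchard trees.
allele	intron1_described	full_length_sequenced	accession_panel	orchard_panel
S_1	TRUE	TRUE	TRUE	TRUE
S_2	TRUE	TRUE	TRUE	FALSE
S_3	TRUE	TRUE	TRUE	FALSE
S_4	TRUE	TRUE	TRUE	TRUE
S_5	TRUE	TRUE	TRUE	FALSE
S_6	TRUE	TRUE	TRUE	TRUE
S_7	TRUE	TRUE	TRUE	FALSE
S_8	TRUE	TRUE	TRUE	TRUE
S_9	TRUE	TRUE	TRUE	TRUE
S_10	TRUE	TRUE	TRUE	TRUE
S_11	TRUE	TRUE	TRUE	FALSE
S_12	FALSE	TRUE	TRUE	FALSE
S_13	FALSE	TRUE	TRUE	FALSE
S_14	FALSE	TRUE	TRUE	FALSE
S_15	FALSE	FALSE	TRUE	FALSE
S_16	FALSE	FALSE	TRUE	FALSE
S_17	FALSE	FALSE	TRUE	FALSE
S_18	FALSE	FALSE	TRUE	FALSE
S_19	FALSE	FALSE	FALSE	TRUE
S_20	FALSE	FALSE	FALSE	TRUE
S_21	FALSE	FALSE	FALSE	TRUE
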