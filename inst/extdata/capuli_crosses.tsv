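# Assisted crosses among the 7 orchard trees with the compatibility class
# expected from their S-genotypes under gametophytic self-incompatibility.
donor	receptor	expected	observed
22	17	incompatible	undetermined
12	13	incompatible	incompatible
17	1	compatible	compatible
14	15	compatible	compatible
17	17	incompatible	undetermined
13	13	incompatible	incompatible
1	1	incompatible	incompatible
15	15	incompatible	incompatible
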