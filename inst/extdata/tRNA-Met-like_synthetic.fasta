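>tRNA-Met-syn synthetic class-I tRNA (76 nt) constructed in-package; V-loop RNase T1 fragment has composition A2 C2 G1 U1 with U at Sprinzl 47
GGCUACGUAGCUCAGUUGGUUAGAGCACAUCACUCAUAAUGUGACCUAGGUUCGAAUCCCGUCGUAGCCACCACCA
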