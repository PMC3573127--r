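>rcrs_window_synthetic 16056-16409 synthetic stand-in reference (not the true rCRS)
CGAGAAACGCAACCCTCACGGCCACACCTGACGAAGAATCTCTGCCCTTCCCCCCTCCAC
TATTACTCACTCATGTTCACAACCACACTACTGGCGTTGTATCCACGTCTTATGGCACAA
TCAAGGAAGACGTATGCTATCCACATACATCTATAGCTACCCTCCACCCTGCGACCATGG
AGACACCCACGACTCAGTCCGAATCCCTATCTAGTTAAAGCATACGATTGTAACGAACAT
AATCCATATCAGAAAGTACACTCAGTATACTATTATCGCTCTCCTAAGAGACACTAACTC
ATATACGACAATTACCGCATAACTAACTTAAGCCACACCTACCGAACACACCAC
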