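wavenumber,t_selected,mit_selected,assignment,reference
1116.4,TRUE,TRUE,"CH2,6 in-plane bend and C1-Calpha-Halpha bend",literature compilation
1201.5,FALSE,TRUE,"Amide III (proteins); Amide III: C-N stretching and N-H bending",literature compilation
1221.1,FALSE,TRUE,"Amide III (beta-sheet); Amide III (proteins)",literature compilation
1234.2,TRUE,TRUE,"Concerted ring mode",literature compilation
1237.9,FALSE,TRUE,"Amide III and CH2 wagging: glycine backbone and proline side chains",literature compilation
1267.6,TRUE,TRUE,"C-H (lipid in healthy tissue); Amide III (collagen assignment)",literature compilation
1272.3,FALSE,TRUE,"CH-alpha' rocking",literature compilation
1290.7,FALSE,TRUE,"Cytosine",literature compilation
1420.5,TRUE,FALSE,"CH2 (lipid and protein); DNA/RNA; deoxyribose (B, Z-marker)",literature compilation
1488.2,TRUE,FALSE,"Guanine (N7); collagen",literature compilation
1578.9,TRUE,FALSE,"Guanine (N3); guanine, adenine",literature compilation
1610.4,TRUE,TRUE,"Cytosine (NH2)",literature compilation
1614.8,FALSE,TRUE,"Tyrosine",literature compilation
1634.0,FALSE,TRUE,"Amide I",literature compilation
1637.5,TRUE,FALSE,"Amide I",literature compilation
1650.5,TRUE,TRUE,"Amide I",literature compilation
1654.9,TRUE,FALSE,"Amide I; C=C stretching; collagen",literature compilation
1660.9,TRUE,TRUE,"Amide I; C=C (lipids, fatty acids); ceramide backbone",literature compilation
1664.4,TRUE,TRUE,"Amide I",literature compilation
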