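# Pan-assay interference (PAINS) patterns (stand-in list).
# A compact set of the most common PAINS motifs — quinones, catechols,
# rhodanines, enamine/azo dyes and related promiscuous scaffolds. One
# SMARTS per line; supply a full published PAINS catalog to reproduce a
# specific screen exactly.
O=C1C=CC(=O)C=C1                        # para-quinone
O=C1C(=O)C=CC=C1                        # ortho-quinone
[OX2H]c1ccc([OX2H])cc1                  # hydroquinone
[OX2H]c1ccccc1[OX2H]                    # catechol
O=C1CSC(=S)N1                           # rhodanine core
O=C1NC(=S)SC1                           # rhodanine (tautomer spelling)
O=C1NC(=O)NC(=O)C1=[CX3]                # alkylidene barbiturate
S=C1NC(=O)NC1=O                         # thiohydantoin
[#6]N=Nc1ccc([OX2H,NX3])cc1             # azo dye with activated ring
[NX3]c1ccc(N=O)cc1                      # para-nitroso aniline
[OX2H]c1ccc(C=[CX3])cc1                 # phenolic styrene (Mannich-type)
C=C1C(=O)NC(=O)S1                       # ene-thiazolidinedione
[CX3](=O)C=C[CX3](=O)                   # 1,4-ene-dione
c1ccc2c(c1)C(=O)c1ccccc1C2=O            # anthraquinone
[NX3H2]c1ccc([NX3H2])cc1                # para-phenylenediamine
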