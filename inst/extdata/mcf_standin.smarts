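# Medicinal-chemistry filter patterns (stand-in list).
# Reactive, unstable or toxicophoric groups commonly excluded when
# assembling screening collections. One SMARTS per line; replace with a
# custom list to reproduce any specific published filter set.
[OX1]=[CX3][F,Cl,Br,I]          # acyl halide
[CX3H1]=O                       # aldehyde
C(=O)OC(=O)                     # anhydride
N=[N+]=[N-]                     # azide
N=N=N                           # azide (uncharged spelling)
[SX2H]                          # thiol
[OX2][OX2]                      # peroxide
[NX3][NX3]                      # hydrazine
N=C=O                           # isocyanate
N=C=S                          # isothiocyanate
[CH2X4][Cl,Br,I]                # primary alkyl halide
C1OC1                           # epoxide
C1NC1                           # aziridine
[CX3](=O)[CX3](=O)              # 1,2-dicarbonyl
[CX3;!R]=[CX3;!R][CX3]=[OX1]    # acyclic Michael acceptor (enone)
[NX2;!R]=[CX3;!R][#6]           # acyclic aldimine/ketimine
S(=O)(=O)[F,Cl,Br]              # sulfonyl halide
[N+](=O)[O-]                    # nitro group
N=[NX2]N                        # triazene
C(=S)N                          # thioamide
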