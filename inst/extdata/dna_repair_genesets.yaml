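# DNA-repair pathway gene sets.
#
# Curated from the KEGG repair pathway maps: base-excision repair,
# nucleotide-excision repair, mismatch repair, homologous recombination,
# and non-homologous end joining, extended with recurrent
# double-strand-break signaling and chromatin-remodeling factors that act
# alongside the HR core machinery (ATM, ATR, SRCAP and relatives).
# Replication factors shared between pathways (polymerases, clamp/clamp
# loader, ligases) appear in every pathway that uses them.
version: kegg-repair-curated-1.0
pathways:
  BER:
    - OGG1
    - NTHL1
    - NEIL1
    - NEIL2
    - NEIL3
    - UNG
    - SMUG1
    - MUTYH
    - MPG
    - TDG
    - MBD4
    - APEX1
    - APEX2
    - POLB
    - POLL
    - POLD1
    - POLD2
    - POLD3
    - POLD4
    - POLE
    - POLE2
    - POLE3
    - POLE4
    - LIG1
    - LIG3
    - XRCC1
    - PCNA
    - FEN1
    - PARP1
    - PARP2
    - PARP3
    - PARP4
    - HMGB1
  NER:
    - XPC
    - RAD23A
    - RAD23B
    - CETN2
    - RBX1
    - CUL4A
    - CUL4B
    - DDB1
    - DDB2
    - XPA
    - RPA1
    - RPA2
    - RPA3
    - RPA4
    - ERCC1
    - ERCC2
    - ERCC3
    - ERCC4
    - ERCC5
    - ERCC6
    - ERCC8
    - GTF2H1
    - GTF2H2
    - GTF2H3
    - GTF2H4
    - GTF2H5
    - CDK7
    - CCNH
    - MNAT1
    - UVSSA
    - XAB2
    - MMS19
    - RFC1
    - RFC2
    - RFC3
    - RFC4
    - RFC5
    - POLD1
    - POLD2
    - POLD3
    - POLD4
    - POLE
    - POLE2
    - POLE3
    - POLE4
    - LIG1
    - PCNA
  MMR:
    - MSH2
    - MSH3
    - MSH6
    - MLH1
    - MLH3
    - PMS1
    - PMS2
    - EXO1
    - RFC1
    - RFC2
    - RFC3
    - RFC4
    - RFC5
    - PCNA
    - RPA1
    - RPA2
    - RPA3
    - RPA4
    - SSBP1
    - POLD1
    - POLD2
    - POLD3
    - POLD4
    - LIG1
  HR:
    - BRCA1
    - BRCA2
    - BARD1
    - PALB2
    - BRIP1
    - RAD50
    - MRE11
    - NBN
    - RAD51
    - RAD51B
    - RAD51C
    - RAD51D
    - RAD51AP1
    - XRCC2
    - XRCC3
    - RAD52
    - RAD54L
    - RAD54B
    - SEM1
    - RBBP8
    - BLM
    - WRN
    - TOP3A
    - TOP3B
    - RMI1
    - RMI2
    - MUS81
    - EME1
    - EME2
    - GEN1
    - SLX1A
    - SLX4
    - ATM
    - ATR
    - ATRX
    - CHEK1
    - CHEK2
    - TOPBP1
    - SRCAP
    - INO80
    - ACTR2
    - RUVBL1
    - RUVBL2
    - RPA1
    - RPA2
    - RPA3
    - POLD1
    - POLD2
    - POLD3
    - POLD4
  NHEJ:
    - PRKDC
    - XRCC6
    - XRCC5
    - LIG4
    - XRCC4
    - NHEJ1
    - DNTT
    - POLM
    - POLL
    - DCLRE1C
    - PAXX
    - APLF
    - PNKP
    - TDP1
    - TDP2
    - MRE11
    - RAD50
    - NBN
    - FEN1
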