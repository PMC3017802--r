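LOCUS       TOYSYN01 1500 bp    DNA     circular   UNA 01-JAN-2026
DEFINITION  Synthetic toy organelle genome for parser and accounting tests.
ACCESSION   TOYSYN01
FEATURES             Location/Qualifiers
     source          1..1500
     gene            101..700
                     /gene="cob"
     CDS             join(101..280,401..700)
                     /gene="cob"
                     /codon_start=1
     intron          281..400
                     /gene="cob_i1"
     gene            complement(801..870)
                     /gene="trnM"
     tRNA            complement(801..870)
                     /gene="trnM"
     gene            901..1000
                     /gene="rrns_S1"
     rRNA            901..1000
                     /gene="rrns_S1"
     gene            1051..1150
                     /gene="rrns_S2"
     rRNA            1051..1150
                     /gene="rrns_S2"
     intron          1201..1280
                     /gene="igi1"
                     /note="intergenic group-II-like intron"
     repeat_region   1301..1400
                     /gene="palcluster_1"
                     /rpt_type="palindromic_cluster"
     gene            join(1451..1500,1..40)
                     /gene="orfX"
                     /pseudo
ORIGIN
        1 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
       61 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      121 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      181 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      241 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      301 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      361 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      421 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      481 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      541 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      601 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      661 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      721 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      781 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      841 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
      901 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
      961 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
     1021 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
     1081 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
     1141 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
     1201 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
     1261 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
     1321 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
     1381 tgcaacgttg caacgttgca acgttgcaac gttgcaacgt tgcaacgttg caacgttgca
     1441 acgttgcaac gttgcaacgt tgcaacgttg caacgttgca acgttgcaac gttgcaacgt
//
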