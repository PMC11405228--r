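LOCUS       SYNMITO                  600 bp    DNA     circular PLN 01-JAN-2024
DEFINITION  synthetic mini mitochondrial genome fixture (generated, not a real
            organism record).
ACCESSION   SYNMITO
FEATURES             Location/Qualifiers
     source          1..600
                     /organism="synthetic construct"
     gene            complement(21..140)
                     /gene="NAD5"
     gene            161..260
                     /gene="rrn18"
     tRNA            281..354
                     /gene="trnM-CAU"
     gene            371..430
                     /gene="atp9"
     gene            441..500
                     /gene="atp9"
     gene            join(561..600,1..10)
                     /gene="cox2"
ORIGIN
        1 taggatgtgt cggctgcata gcagccattg ttaatcacac ttgttaacga atggtcgtgg
       61 ccgccgatcc acgcctaagc gcccacttaa gcgaactaaa aatcgtaagc aagccccttg
      121 taagacttga gtatgttctg cactcatgat atgcaaggtc cgcgtctcag gctgccgccg
      181 cgtataaaga aatactgcat ggtacacagt tcttagttca tttttacacc atatagttct
      241 acaaattagt atactgccaa aggttcagcg agctctcgta aataatgggt tcgctttcta
      301 aagaagggta acgacgtagg ttgtacagag cgaaaatgaa gctagccagg catatgcgaa
      361 caaattgggc agtttctgca gtgacggaac taaccgtata tcacgcacca cgtagcgtta
      421 ccatgttccg gcgttggtct ccggtccata ttcgttggtt ctctagcgga ttggttcgta
      481 gataaggatg aaagtcgaat tgttcgtgaa agttccaatg tgaacgttcg cggttagtaa
      541 ctttacgcat gcgaagtgac acacgacacg agtcctattt ttcatcgtgc gtttgatcta
//
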