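PMID- 100001
TI  - Mitochondrial kinase signalling in cardiomyocyte stress responses.
AB  - Cardiomyocytes respond to oxidative stress through kinase cascades.
      The mitochondrial kinase network integrates calcium signals. Kinase
      inhibition protects cardiomyocytes from apoptosis.
AU  - Nováková E
AU  - Smith JD
JT  - J Card Res
DP  - 2004 Mar-Apr
PMID- 100002
TI  - Genome assembly of a thermophilic archaeon.
AB  - We report the assembly of a thermophilic archaeon genome. Long reads
      resolved repeat regions. Annotation identified heat-stable enzymes.
AU  - Smith JD
AU  - O'Brien-Kelly P
JT  - J Microb Genomics
DP  - 2008 Jan
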