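{
  "locus_id": "FAME3_MARCH6_intron1",
  "left_flank": "TGCGTCTCAGATCAGATAAGCCTCTTGATATACATTGAGTCCCCACAAACTCCGTGAGATTAAAACCTGAATCCCAAAGAGTACCCCGAACTCGTCATCAGGTGCCATGCTCGCCCAATTTGGGACAACTAGTTGAGATTGATTATTAAGTTTACAAAACAACCATACAGATACGATGCGCGCGCGCGGGGCAAATGTTCGGAGCAGTATACTCTGCCTGTAGTACAGACTTATTACACTTTGGACTGGAGTACTCAAATTCAAGCTATGCTTGGAAGCTTCGATACCTGCAAGGTCGAG",
  "right_flank": "TCTTAATGATATAGAATGATCCCCAGCACCTGTATTCTCACGGACTGCCGCTTGATTCGTAATTACAGTTCTTTGTGAGCAGATGTTTAACCCGCTCGAATTAAGTATTTCAAGGGCCACCAAGCAACTTGAGTTCATCCCTTAGCTTGGGCCCTCTTACCATACACATTGAAAAACAACCTTTATCGTCGTTAGATAGGTGTCCCTTGAGATAACGATGAACCGTGCTATACATATTGCATTCACTTTTAACTGACGCTCAATGGTAAGTTTGTCGATACTAATGTAAAGTACAATTCC",
  "motifs": ["TTTTA", "TTTCA"],
  "ref_assembly": "GRCh37",
  "chrom": "chr5",
  "ref_start": 10356460,
  "ref_end": 10356519,
  "thresholds": {
    "normal_max_kb": 5.5,
    "pathogenic_min_kb": 8.5
  }
}
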