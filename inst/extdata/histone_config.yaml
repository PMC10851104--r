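# Histone recognition configuration.
#
# Keyword matching on chain entity names runs first (case-insensitive
# substring match); unmatched protein chains fall back to global sequence
# identity against the per-type reference sequence (canonical human
# sequences), accepted at identity_threshold. Edit freely: the keyword lists
# are a practical approximation, not a closed vocabulary.
identity_threshold: 0.6
types:
  H3:
    keywords:
      - "histone h3"
      - "h3.1"
      - "h3.2"
      - "h3.3"
      - "h3 "
      - "cenp-a"
      - "centromeric histone"
    reference: "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTELLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIMPKDIQLARRIRGERA"
  H4:
    keywords:
      - "histone h4"
      - "h4 "
    reference: "SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLKVFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG"
  H2A:
    keywords:
      - "histone h2a"
      - "h2a.z"
      - "h2a.x"
      - "macro-h2a"
      - "macroh2a"
      - "h2a type"
    reference: "SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGKVTIAQGGVLPNIQAVLLPKKTESHHKAKGK"
  H2B:
    keywords:
      - "histone h2b"
      - "h2b type"
    reference: "PEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTKYTSSK"
  H1:
    keywords:
      - "histone h1"
      - "linker histone"
      - "histone h5"
    reference: "SETAPAAPAAPAPAEKTPVKKKARKSAGAAKRKASGPPVSELITKAVAASKERSGVSLAALKKALAAAGYDVEKNNSRIKLGLKSLVSKGTLVQTKGTGASGSFKLNKKAASGEAKPKAKKAGAAKAKKPAGAAKKPKKATGAATPKKSAKKTPKKAKKPAAAAGAKKAKSPKKAKAAKPKKAPKSPAKAKAVKPKAAKPKTAKPKAAKPKKAAAKKK"
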