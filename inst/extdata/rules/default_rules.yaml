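# Default marker-gene rule set (placeholder lists from standard mouse
# nomenclature; replace with curated lists for real analyses).
hox_genes:
  - Hoxa1
  - Hoxa2
  - Hoxa3
  - Hoxa4
  - Hoxa5
  - Hoxa6
  - Hoxa7
  - Hoxa9
  - Hoxa10
  - Hoxb1
  - Hoxb2
  - Hoxb3
  - Hoxb4
  - Hoxb5
  - Hoxb6
  - Hoxb7
  - Hoxb8
  - Hoxb9
  - Hoxc4
  - Hoxc5
  - Hoxc6
  - Hoxc8
  - Hoxc9
  - Hoxd1
  - Hoxd3
  - Hoxd4
  - Hoxd8
  - Hoxd9
brain_markers:
  - Otx2
  - Otx1
  - En1
  - En2
  - Six3
  - Six6
  - Foxg1
  - Emx2
  - Pax6
  - Lhx2
  - Lhx5
  - Fezf2
  - Barhl2
  - Wnt8b
  - Rax
  - Sfrp2
  - Fgf8
  - Pax2
  - Pax5
  - Dmbx1
  - Sox21
  - Nkx2-1
  - Dlx2
  - Arx
  - Emx1
  - Fezf1
  - Hesx1
  - Lhx1
  - Wnt7b
  - Sfrp1
brain_min_markers: 5
spinal_exclusion_gene: Fgfbp3
dv_modules:
  dorsal:
    - Pax3
    - Pax7
    - Msx1
  midline:
    - Shh
    - Foxa2
    - Ntn1
  ventral:
    - Olig2
    - Nkx2-2
    - Nkx6-1
expressed_threshold: 1
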