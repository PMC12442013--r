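# POPE (1-palmitoyl-2-oleoyl-sn-glycero-3-phosphoethanolamine), CHARMM36-style
# atom nomenclature.  Group boundaries: headgroup runs from the ethanolamine top
# down to and including the phosphorus; glycerol from the phosphoester
# oxygen to the ester oxygens; tails from the carbonyl carbons outward.
species: POPE
groups:
  headgroup: [N, C12, C11, P, O13, O14, O12]
  glycerol: [O11, C1, C2, C3, O21, O31]
  tails: [C21, O22, C22, C23, C24, C25, C26, C27, C28, C29, C210, C211,
          C212, C213, C214, C215, C216, C217, C218,
          C31, O32, C32, C33, C34, C35, C36, C37, C38, C39, C310, C311,
          C312, C313, C314, C315, C316]
phosphorus_atom: P
po4_atoms: [P, O11, O12, O13, O14]
ch_pairs:
  C11: [[C11, H11A], [C11, H11B]]
  C12: [[C12, H12A], [C12, H12B]]
  C1: [[C1, HA], [C1, HB]]
  C2: [[C2, HS]]
  C3: [[C3, HX], [C3, HY]]
  C22: [[C22, H2R], [C22, H2S]]
  C23: [[C23, H3R], [C23, H3S]]
  C24: [[C24, H4R], [C24, H4S]]
  C25: [[C25, H5R], [C25, H5S]]
  C26: [[C26, H6R], [C26, H6S]]
  C27: [[C27, H7R], [C27, H7S]]
  C28: [[C28, H8R], [C28, H8S]]
  C29: [[C29, H91]]
  C210: [[C210, H101]]
  C211: [[C211, H11R], [C211, H11S]]
  C212: [[C212, H12R], [C212, H12S]]
  C213: [[C213, H13R], [C213, H13S]]
  C214: [[C214, H14R], [C214, H14S]]
  C215: [[C215, H15R], [C215, H15S]]
  C216: [[C216, H16R], [C216, H16S]]
  C217: [[C217, H17R], [C217, H17S]]
  C218: [[C218, H18R], [C218, H18S], [C218, H18T]]
  C32: [[C32, H2X], [C32, H2Y]]
  C33: [[C33, H3X], [C33, H3Y]]
  C34: [[C34, H4X], [C34, H4Y]]
  C35: [[C35, H5X], [C35, H5Y]]
  C36: [[C36, H6X], [C36, H6Y]]
  C37: [[C37, H7X], [C37, H7Y]]
  C38: [[C38, H8X], [C38, H8Y]]
  C39: [[C39, H9X], [C39, H9Y]]
  C310: [[C310, H10X], [C310, H10Y]]
  C311: [[C311, H11X], [C311, H11Y]]
  C312: [[C312, H12X], [C312, H12Y]]
  C313: [[C313, H13X], [C313, H13Y]]
  C314: [[C314, H14X], [C314, H14Y]]
  C315: [[C315, H15X], [C315, H15Y]]
  C316: [[C316, H16X], [C316, H16Y], [C316, H16Z]]
hbond_atoms:
  HN1: {role: donor_H, capacity: 1, bonded_to: N, group: headgroup}
  HN2: {role: donor_H, capacity: 1, bonded_to: N, group: headgroup}
  HN3: {role: donor_H, capacity: 1, bonded_to: N, group: headgroup}
  O13: {role: acceptor, capacity: 3}   # charged phosphate oxygen
  O14: {role: acceptor, capacity: 3}
  O11: {role: acceptor, capacity: 2}   # neutral ester oxygens
  O12: {role: acceptor, capacity: 2}
  O21: {role: acceptor, capacity: 2}
  O22: {role: acceptor, capacity: 2}
  O31: {role: acceptor, capacity: 2}
  O32: {role: acceptor, capacity: 2}
segments:
  C11: headgroup
  C12: headgroup
  C1: headgroup
  C2: headgroup
  C3: headgroup
  C22: sn-2
  C23: sn-2
  C24: sn-2
  C25: sn-2
  C26: sn-2
  C27: sn-2
  C28: sn-2
  C29: sn-2
  C210: sn-2
  C211: sn-2
  C212: sn-2
  C213: sn-2
  C214: sn-2
  C215: sn-2
  C216: sn-2
  C217: sn-2
  C218: sn-2
  C32: sn-1
  C33: sn-1
  C34: sn-1
  C35: sn-1
  C36: sn-1
  C37: sn-1
  C38: sn-1
  C39: sn-1
  C310: sn-1
  C311: sn-1
  C312: sn-1
  C313: sn-1
  C314: sn-1
  C315: sn-1
  C316: sn-1
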