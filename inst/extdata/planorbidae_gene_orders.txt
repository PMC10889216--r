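# Circular signed mitochondrial gene orders of the 15-genome ramshorn-snail panel.
# One line per genome: accession followed by signed gene tokens (+ = major strand).
# Listed in arrangement-type order (A..F by first appearance).
#
# Provenance per arrangement type:
#   type E (OR684570, Polypylis sp. TS-2018): read directly from the annotation
#     coordinates and strands of the packaged 37-gene fixture.
#   type D (OX421510, Anisus vortex): type E with rrnS in its minor-strand state
#     (the rrnS reverse transposition is specific to Polypylis and Gyraulus).
#   type B (Bulinus truncatus, five Biomphalaria, two Planorbella): type D with
#     trnW and trnC returned from the nad4L-cob junction to their type-B
#     positions (trnW between trnY and trnG; trnC after cob's trnD).
#   type A (Bulinus globosus/nasutus/ugandae): type B with trnD away from the
#     cob-trnC junction; its type-A position (between trnF and cox2) is a
#     SYNTHETIC choice, not stated by the source annotations.
#   type C (EF433576, Biomphalaria tenagophila): type B with trnE, trnL2, trnM,
#     trnN, trnQ, trnR, trnS2 in reversed orientation.
#   type F (MW357851, Gyraulus sp.): type E with trnQ reversed; its placement
#     (in situ between trnH and trnL2) is a SYNTHETIC choice.
MK414453 +nad6 +nad5 +nad1 +nad4L +cob +trnC +trnF +trnD +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MK414450 +nad6 +nad5 +nad1 +nad4L +cob +trnC +trnF +trnD +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MK414451 +nad6 +nad5 +nad1 +nad4L +cob +trnC +trnF +trnD +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MK414449 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MG431964 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
NC_005439 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MG431962 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MF480756 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MG431963 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
KY514384 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MW889961 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
EF433576 +nad6 +nad5 +nad1 +nad4L +cob +trnD +trnC +trnF +cox2 +trnY +trnW +trnG +trnH +trnQ +trnL2 -atp8 +trnN -atp6 +trnR +trnE -rrnS +trnM -nad3 +trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
OX421510 +nad6 +nad5 +nad1 +nad4L +trnW +trnC +cob +trnD +trnF +cox2 +trnY +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE -rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
OR684570 +nad6 +nad5 +nad1 +nad4L +trnW +trnC +cob +trnD +trnF +cox2 +trnY +trnG +trnH -trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE +rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
MW357851 +nad6 +nad5 +nad1 +nad4L +trnW +trnC +cob +trnD +trnF +cox2 +trnY +trnG +trnH +trnQ -trnL2 -atp8 -trnN -atp6 -trnR -trnE +rrnS -trnM -nad3 -trnS2 +trnS1 +nad4 -trnT -cox3 +trnI +nad2 +trnK +cox1 +trnV +rrnL +trnL1 +trnA +trnP
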