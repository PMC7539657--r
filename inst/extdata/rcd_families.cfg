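family: ZEN1_ENDOG_NUC1
category: apoptosis
pathway: nuclease
mode: combined
expr: PF02265 / PF01223 / PF03265
baits: ZEN1_ENDOG_NUC1

family: AIF_AMID
category: apoptosis
pathway: oxidoreductase
mode: homology_only
baits: AIF_AMID

family: HTRA
category: apoptosis
pathway: protease
mode: combined
expr: PF13365 + PF00595 / PF12812 / PF13180 / PF17815 / PF17820
baits: HTRA

family: METACASPASE
category: apoptosis
pathway: protease
mode: combined
expr: PF00656
baits: METACASPASE

family: TSN
category: apoptosis
pathway: metacaspase_substrate
mode: combined
expr: PF00565 + PF00567
baits: TSN

family: BAX_INHIBITOR
category: apoptosis
pathway: inhibitor
mode: domain_only
expr: PF01027

family: API5
category: apoptosis
pathway: inhibitor
mode: domain_only
expr: PF05918

family: DAD
category: apoptosis
pathway: inhibitor
mode: domain_only
expr: PF02109

family: BIR
category: apoptosis
pathway: inhibitor
mode: domain_only
expr: PF00653

family: NB_ARC_NACHT
category: apoptosis
pathway: adaptor
mode: domain_only
expr: PF00931 / PF05729

family: ATG1
category: autophagy
pathway: induction
mode: domain_only
expr: PF12063

family: ATG13
category: autophagy
pathway: induction
mode: domain_only
expr: PF10033

family: ATG101
category: autophagy
pathway: induction
mode: domain_only
expr: PF07855

family: TOR
category: autophagy
pathway: induction
mode: combined
expr: PF08771
baits: TOR

family: ATG11
category: autophagy
pathway: cargo_selection
mode: domain_only
expr: PF10377

family: ATG6_BECLIN
category: autophagy
pathway: cargo_selection
mode: domain_only
expr: PF04111 / PF17675

family: ATG3_10
category: autophagy
pathway: vesicle_expansion
mode: domain_only
expr: PF03986 / PF03987 / PF10381

family: ATG4
category: autophagy
pathway: vesicle_expansion
mode: domain_only
expr: PF03416

family: ATG5
category: autophagy
pathway: vesicle_expansion
mode: domain_only
expr: PF04106

family: ATG7
category: autophagy
pathway: vesicle_expansion
mode: domain_only
expr: PF16420

family: ATG8
category: autophagy
pathway: vesicle_expansion
mode: domain_only
expr: PF02991

family: ATG12
category: autophagy
pathway: vesicle_expansion
mode: domain_only
expr: PF04110

family: RIPK1_3
category: necrosis
pathway: necroptosis
mode: combined
expr: PF12721 / PF00531
baits: RIPK1_3

family: GSDMD
category: necrosis
pathway: pyroptosis
mode: combined
expr: PF04598 / PF17708
baits: GSDMD

family: MLKL
category: necrosis
pathway: necroptosis
mode: homology_only
baits: MLKL
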