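nodes:
- name: L_IFG
  mni:
  - -54.0
  - 12.0
  - 18.0
  hidden: no
- name: R_IFG
  mni:
  - 54.0
  - 12.0
  - 18.0
  hidden: no
- name: L_DLPFC
  mni:
  - -37.0
  - 27.0
  - 39.0
  hidden: no
- name: R_DLPFC
  mni:
  - 37.0
  - 27.0
  - 39.0
  hidden: no
- name: preSMA_dACC
  mni:
  - 0.0
  - -6.0
  - 56.0
  hidden: no
- name: BG
  mni: ~
  hidden: yes
input_nodes:
- L_IFG
- R_IFG
- L_DLPFC
- R_DLPFC
edges:
- from: L_IFG
  to: L_DLPFC
  type: forward
  directed: yes
- from: L_DLPFC
  to: L_IFG
  type: backward
  directed: yes
- from: R_IFG
  to: R_DLPFC
  type: forward
  directed: yes
- from: R_DLPFC
  to: R_IFG
  type: backward
  directed: yes
- from: L_DLPFC
  to: preSMA_dACC
  type: backward
  directed: yes
- from: R_DLPFC
  to: preSMA_dACC
  type: backward
  directed: yes
- from: preSMA_dACC
  to: BG
  type: lateral
  directed: yes
- from: BG
  to: preSMA_dACC
  type: lateral
  directed: yes
- from: L_IFG
  to: BG
  type: lateral
  directed: yes
- from: BG
  to: L_IFG
  type: lateral
  directed: yes
- from: R_IFG
  to: BG
  type: lateral
  directed: yes
- from: BG
  to: R_IFG
  type: lateral
  directed: yes
- from: L_IFG
  to: R_IFG
  type: lateral
  directed: no
- from: L_DLPFC
  to: R_DLPFC
  type: lateral
  directed: no
models:
  IFG_afferent:
  - L_IFG->BG
  - R_IFG->BG
  IFG_efferent:
  - BG->L_IFG
  - BG->R_IFG
  IFG_both:
  - L_IFG->BG
  - R_IFG->BG
  - BG->L_IFG
  - BG->R_IFG
  preSMA_afferent: preSMA_dACC->BG
  preSMA_efferent: BG->preSMA_dACC
  preSMA_both:
  - preSMA_dACC->BG
  - BG->preSMA_dACC
  both_afferent:
  - L_IFG->BG
  - R_IFG->BG
  - preSMA_dACC->BG
  both_efferent:
  - BG->L_IFG
  - BG->R_IFG
  - BG->preSMA_dACC
  both_both:
  - L_IFG->BG
  - R_IFG->BG
  - BG->L_IFG
  - BG->R_IFG
  - preSMA_dACC->BG
  - BG->preSMA_dACC
families:
  IFG:
  - IFG_afferent
  - IFG_efferent
  - IFG_both
  preSMA:
  - preSMA_afferent
  - preSMA_efferent
  - preSMA_both
  both:
  - both_afferent
  - both_efferent
  - both_both

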