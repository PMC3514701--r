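n_subjects: 1062
pattern_probs:
  R: 0.206
  LS: 0.034
  TL: 0.043
  TL_LS: 0.043
  CT: 0.17
  CT_LS: 0.17
  CT_TL: 0.228
  CT_TL_LS: 0.106
system_params:
- system: BP
  slope: 0.12
  target_n: 68
- system: CV
  slope: 0.12
  target_n: 216
- system: CF
  slope: 0.36
  target_n: 64
- system: DS
  slope: 0.19
  target_n: 110
- system: LD
  slope: 0.17
  target_n: 146
- system: MS
  slope: 0.11
  target_n: 28
- system: NS
  slope: 0.07
  target_n: 121
- system: SK
  slope: 0.31
  target_n: 115
- system: UG
  slope: 0.11
  target_n: 168
- system: VBW
  slope: 0.18
  target_n: 23
missingness:
  BP: 0.12
  CV: 0.12
  CF: 0.12
  DS: 0.12
  LD: 0.12
  MS: 0.12
  NS: 0.12
  SK: 0.12
  UG: 0.12
  VBW: 0.12
ct_anterior_prob: 0.855
tl_anterior_prob: 0.8
bilateral_prob: 0.5
rudimentary_vs_absent_prob: 0.6
tp_enlarged_prob: 0.1
thoracic_identity_prob: 0.02
ls_mode_probs:
  minus: 0.45
  plus: 0.35
  flag: 0.2
sex_probs:
  male: 0.5546139
  female: 0.433145
  unknown: 0.0122411
ga_mean: 26.6
ga_sd: 10.4
ga_range:
- 13.0
- 92.0
seed: 1
coding_map:
- term: lung_hypoplasia
  primary: BP
  layers: endoderm
- term: congenital_cystic_lung
  primary: BP
  layers: endoderm
- term: ventricular_septal_defect
  primary: CV
  layers: mesoderm
- term: hypoplastic_left_heart
  primary: CV
  layers: mesoderm
- term: transposition_great_arteries
  primary: CV
  layers: mesoderm
  processes: left_right
- term: dextrocardia
  primary: CV
  layers: mesoderm
  processes: left_right
- term: common_arterial_trunk
  primary: CV
  layers: mesoderm
  processes: neural_crest
- term: cleft_lip
  primary: CF
  layers: ectoderm
  processes:
  - neural_crest
  - midline
- term: cleft_palate
  primary: CF
  layers: ectoderm
  processes: neural_crest
- term: micrognathia
  primary: CF
  layers: ectoderm
  processes: neural_crest
- term: ear_tag
  primary: CF
  layers: ectoderm
  processes: neural_crest
- term: TE_fistula
  primary: DS
  secondary: BP
  layers: endoderm
  processes: midline
- term: duodenal_atresia
  primary: DS
  layers: endoderm
- term: anal_atresia
  primary: DS
  layers: endoderm
- term: intestinal_malrotation
  primary: DS
  layers: endoderm
  processes: left_right
- term: limb_reduction
  primary: LD
  secondary: SK
  layers: mesoderm
- term: polydactyly
  primary: LD
  secondary: SK
  layers: mesoderm
- term: syndactyly
  primary: LD
  layers: mesoderm
- term: club_foot
  primary: LD
  layers: mesoderm
- term: diaphragmatic_hernia
  primary: MS
  layers: mesoderm
- term: muscular_hypoplasia
  primary: MS
  layers: mesoderm
- term: holoprosencephaly
  primary: NS
  secondary: CF
  layers: ectoderm
  processes:
  - midline
  - neural_crest
- term: anencephaly
  primary: NS
  layers: ectoderm
  processes: midline
- term: spina_bifida
  primary: NS
  layers: ectoderm
  processes: midline
- term: hydrocephalus
  primary: NS
  layers: ectoderm
- term: skeletal_dysplasia
  primary: SK
  secondary:
  - LD
  - CF
  layers: mesoderm
- term: hemivertebrae
  primary: SK
  layers: mesoderm
  processes: segmentation
- term: fused_ribs
  primary: SK
  layers: mesoderm
  processes: segmentation
- term: fused_vertebrae
  primary: SK
  layers: mesoderm
  processes: segmentation
- term: renal_agenesis
  primary: UG
  layers: mesoderm
- term: hydronephrosis
  primary: UG
  layers: mesoderm
- term: horseshoe_kidney
  primary: UG
  layers: mesoderm
- term: hypospadias
  primary: UG
  layers: endoderm
- term: omphalocele
  primary: VBW
  layers: mesoderm
  processes: midline
- term: gastroschisis
  primary: VBW
  layers: mesoderm
- term: bladder_exstrophy
  primary: VBW
  layers: mesoderm
  processes: midline
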