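# Default PROM catalog: 18 validated spine/pain patient-reported outcome
# measures (a seed list of 15 plus 3 added during refinement). Only a handful
# of instruments are fixed by the package's validation corpus (the Oswestry
# Disability Index and the back and neck Bournemouth Questionnaires); the
# remainder are widely used instruments and should be aligned with the local
# instrument list before production use.
#
# Unidimensional pain scales (NRS/VAS families) are excluded by policy: any
# surface form listed under excluded_measures never compiles to a pattern.
definitions:
  - prom_id: odi
    canonical_name: Oswestry Disability Index
    aliases:
      - Oswestry Disability Questionnaire
      - Oswestry
    abbreviations: [ODI]
    allow_fuzzy: true
    category: function
  - prom_id: bournemouth_back
    canonical_name: Bournemouth Questionnaire back
    aliases:
      - Bournemouth Questionnaire
      - Back Bournemouth Questionnaire
      - Bournemouth back
    abbreviations: [BQB]
    allow_fuzzy: true
    category: multidimensional
  - prom_id: bournemouth_neck
    canonical_name: Bournemouth Questionnaire neck
    aliases:
      - Neck Bournemouth Questionnaire
      - Bournemouth Questionnaire - neck
      - Bournemouth neck
    abbreviations: [BQN]
    allow_fuzzy: true
    category: multidimensional
  - prom_id: ndi
    canonical_name: Neck Disability Index
    aliases: []
    abbreviations: [NDI]
    allow_fuzzy: true
    category: function
  - prom_id: rmdq
    canonical_name: Roland-Morris Disability Questionnaire
    aliases:
      - Roland Morris Disability Questionnaire
      - Roland-Morris Questionnaire
    abbreviations: [RMDQ, RDQ]
    allow_fuzzy: true
    category: function
  - prom_id: promis_pi
    canonical_name: PROMIS Pain Interference
    aliases: []
    abbreviations: []
    allow_fuzzy: true
    category: pain
  - prom_id: promis_pf
    canonical_name: PROMIS Physical Function
    aliases: []
    abbreviations: []
    allow_fuzzy: true
    category: function
  - prom_id: peg
    canonical_name: Pain Enjoyment General Activity Scale
    aliases:
      - PEG scale
    abbreviations: [PEG]
    allow_fuzzy: false
    category: pain
  - prom_id: psfs
    canonical_name: Patient-Specific Functional Scale
    aliases:
      - Patient Specific Functional Scale
    abbreviations: [PSFS]
    allow_fuzzy: true
    category: function
  - prom_id: fabq
    canonical_name: Fear-Avoidance Beliefs Questionnaire
    aliases:
      - Fear Avoidance Beliefs Questionnaire
    abbreviations: [FABQ]
    allow_fuzzy: true
    category: psychosocial
  - prom_id: pcs
    canonical_name: Pain Catastrophizing Scale
    aliases: []
    abbreviations: [PCS]
    allow_fuzzy: true
    category: psychosocial
  - prom_id: bpi
    canonical_name: Brief Pain Inventory
    aliases: []
    abbreviations: [BPI]
    allow_fuzzy: true
    category: pain
  - prom_id: start_back
    canonical_name: STarT Back Screening Tool
    aliases:
      - STarT Back Tool
      - Keele STarT Back
    abbreviations: [SBST]
    allow_fuzzy: true
    category: screening
  - prom_id: qbpds
    canonical_name: Quebec Back Pain Disability Scale
    aliases:
      - Quebec Disability Scale
    abbreviations: [QBPDS]
    allow_fuzzy: true
    category: function
  - prom_id: pseq
    canonical_name: Pain Self-Efficacy Questionnaire
    aliases:
      - Pain Self Efficacy Questionnaire
    abbreviations: [PSEQ]
    allow_fuzzy: true
    category: psychosocial
  # Added during refinement
  - prom_id: uefi
    canonical_name: Upper Extremity Functional Index
    aliases: []
    abbreviations: [UEFI]
    allow_fuzzy: true
    category: function
  - prom_id: lefs
    canonical_name: Lower Extremity Functional Scale
    aliases: []
    abbreviations: [LEFS]
    allow_fuzzy: true
    category: function
  - prom_id: hit6
    canonical_name: Headache Impact Test
    aliases:
      - Headache Impact Test-6
    abbreviations: [HIT-6]
    allow_fuzzy: true
    category: headache
excluded_measures:
  - Numerical Rating Scale
  - Numeric Rating Scale
  - Numeric Pain Rating Scale
  - NRS
  - NPRS
  - Visual Analog Scale
  - Visual Analogue Scale
  - VAS
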