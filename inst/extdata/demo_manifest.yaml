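lexicon:
  acuity_keywords:
    '0':
    - discharge home
    - home with instructions
    - outpatient follow-up
    '1':
    - ed observation
    - re-evaluation in the emergency department
    - observe and recheck
    '2':
    - admit to the ward
    - monitored admission
    - admit to hcu
    - admit to ccu
    '3':
    - admit to icu
    - immediate resuscitation
    - emergency intervention
    - take to the operating room
  trigger_symptom_keywords:
  - worsening pain
  - shortness of breath
  - high fever
  - repeated vomiting
  - fainting
  - new weakness
  - confusion
  urgency_keywords:
  - immediately
  - right away
  - call 911
  - as soon as possible
  time_window_patterns:
  - within 24 hours
  - within 48 hours
  - within 2 days
  care_site_keywords:
  - emergency department
  - nearest hospital
  order_marker_keywords:
  - first
  - then
  - before
  - after
trap_rules:
- rule_id: CP07
  severity_on_trigger: 2
  forbidden_keywords:
  - aspirin
  - heparin
  - anticoagulation
  - clopidogrel
  - antiplatelet
  exclusion_caveat_keywords:
  - dissection excluded
  - ct angiography
  - rule out dissection
  - transesophageal echocardiography
  required_precedence: ~
  required_action_keywords: []
- rule_id: AP07
  severity_on_trigger: 3
  forbidden_keywords:
  - heparin
  - anticoagulation
  - thrombolysis
  exclusion_caveat_keywords:
  - rupture excluded
  - vascular surgery consult
  - definitive imaging
  required_precedence: ~
  required_action_keywords: []
- rule_id: HA07
  severity_on_trigger: 3
  forbidden_keywords: []
  exclusion_caveat_keywords: []
  required_precedence:
    first:
    - head ct
    - head imaging
    - brain ct
    then: lumbar puncture
  required_action_keywords: []
- rule_id: DY07
  severity_on_trigger: 3
  forbidden_keywords: []
  exclusion_caveat_keywords: []
  required_precedence: ~
  required_action_keywords:
  - intramuscular epinephrine
  - im epinephrine
  - epinephrine
vignettes:
- vignette_id: CP01
  category: chest pain
  is_pair_member: no
  base_acuity: 0
- vignette_id: AP01
  category: abdominal pain
  is_pair_member: no
  base_acuity: 0
- vignette_id: HA01
  category: headache
  is_pair_member: no
  base_acuity: 0
- vignette_id: DY01
  category: dyspnea
  is_pair_member: no
  base_acuity: 0
- vignette_id: CP02
  category: chest pain
  is_pair_member: no
  base_acuity: 0
- vignette_id: AP02
  category: abdominal pain
  is_pair_member: no
  base_acuity: 0
- vignette_id: HA02
  category: headache
  is_pair_member: no
  base_acuity: 0
- vignette_id: DY02
  category: dyspnea
  is_pair_member: no
  base_acuity: 0
- vignette_id: CP03
  category: chest pain
  is_pair_member: no
  base_acuity: 1
- vignette_id: AP03
  category: abdominal pain
  is_pair_member: no
  base_acuity: 1
- vignette_id: HA03
  category: headache
  is_pair_member: no
  base_acuity: 1
- vignette_id: DY03
  category: dyspnea
  is_pair_member: no
  base_acuity: 1
- vignette_id: CP04
  category: chest pain
  is_pair_member: no
  base_acuity: 1
- vignette_id: AP04
  category: abdominal pain
  is_pair_member: no
  base_acuity: 1
- vignette_id: HA04
  category: headache
  is_pair_member: no
  base_acuity: 1
- vignette_id: DY04
  category: dyspnea
  is_pair_member: no
  base_acuity: 1
- vignette_id: CP05
  category: chest pain
  is_pair_member: no
  base_acuity: 2
- vignette_id: AP05
  category: abdominal pain
  is_pair_member: no
  base_acuity: 2
- vignette_id: HA05
  category: headache
  is_pair_member: no
  base_acuity: 2
- vignette_id: DY05
  category: dyspnea
  is_pair_member: no
  base_acuity: 2
- vignette_id: CP06
  category: chest pain
  is_pair_member: no
  base_acuity: 2
- vignette_id: AP06
  category: abdominal pain
  is_pair_member: no
  base_acuity: 2
- vignette_id: HA06
  category: headache
  is_pair_member: no
  base_acuity: 2
- vignette_id: DY06
  category: dyspnea
  is_pair_member: no
  base_acuity: 2
- vignette_id: CP07
  category: chest pain
  trap_rule_id: CP07
  is_pair_member: no
  base_acuity: 2
- vignette_id: AP07
  category: abdominal pain
  trap_rule_id: AP07
  is_pair_member: no
  base_acuity: 2
- vignette_id: HA07
  category: headache
  trap_rule_id: HA07
  is_pair_member: no
  base_acuity: 2
- vignette_id: DY07
  category: dyspnea
  trap_rule_id: DY07
  is_pair_member: no
  base_acuity: 2
- vignette_id: PR01B
  category: chest pain
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR01W
  category: chest pain
  is_pair_member: yes
  base_acuity: 2
- vignette_id: PR02B
  category: abdominal pain
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR02W
  category: abdominal pain
  is_pair_member: yes
  base_acuity: 2
- vignette_id: PR03B
  category: headache
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR03W
  category: headache
  is_pair_member: yes
  base_acuity: 2
- vignette_id: PR04B
  category: dyspnea
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR04W
  category: dyspnea
  is_pair_member: yes
  base_acuity: 3
- vignette_id: PR05B
  category: chest pain
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR05W
  category: chest pain
  is_pair_member: yes
  base_acuity: 2
- vignette_id: PR06B
  category: abdominal pain
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR06W
  category: abdominal pain
  is_pair_member: yes
  base_acuity: 2
- vignette_id: PR07B
  category: headache
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR07W
  category: headache
  is_pair_member: yes
  base_acuity: 2
- vignette_id: PR08B
  category: dyspnea
  is_pair_member: yes
  base_acuity: 1
- vignette_id: PR08W
  category: dyspnea
  is_pair_member: yes
  base_acuity: 3
pairs:
- pair_id: PR01
  base_vignette_id: PR01B
  worse_vignette_id: PR01W
  min_required_acuity_worse: 2
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR02
  base_vignette_id: PR02B
  worse_vignette_id: PR02W
  min_required_acuity_worse: 2
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR03
  base_vignette_id: PR03B
  worse_vignette_id: PR03W
  min_required_acuity_worse: 2
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR04
  base_vignette_id: PR04B
  worse_vignette_id: PR04W
  min_required_acuity_worse: 3
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR05
  base_vignette_id: PR05B
  worse_vignette_id: PR05W
  min_required_acuity_worse: 2
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR06
  base_vignette_id: PR06B
  worse_vignette_id: PR06W
  min_required_acuity_worse: 2
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR07
  base_vignette_id: PR07B
  worse_vignette_id: PR07W
  min_required_acuity_worse: 2
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
- pair_id: PR08
  base_vignette_id: PR08B
  worse_vignette_id: PR08W
  min_required_acuity_worse: 3
  required_action_groups:
  - - iv fluids
    - fluid resuscitation
  - - supplemental oxygen
    - oxygen therapy
thresholds:
  safety_net_threshold: 3
  admission_min_level: 2
  severity_weights:
    m1: 2
    m2: 3
    m3: 2
    m4: 1
field_mapping: ~
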