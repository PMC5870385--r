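{
  "version": "1.0-reconstruction",
  "entry": "danger_drink",
  "question_cap": 15,
  "age_limits": [1, 180],
  "nodes": [
    {
      "id": "danger_drink",
      "prompt_id": "q_danger_drink",
      "block": "danger_signs",
      "routes": {"yes": "danger_convulsions", "no": "danger_convulsions"},
      "emissions": {"yes": ["inability_to_drink"], "no": []},
      "ask_only": true
    },
    {
      "id": "danger_convulsions",
      "prompt_id": "q_convulsions",
      "block": "danger_signs",
      "routes": {"yes": "fever", "no": "fever"},
      "emissions": {"yes": ["neurological_emergency"], "no": []},
      "ask_only": true
    },
    {
      "id": "fever",
      "prompt_id": "q_fever",
      "block": "fever",
      "routes": {"yes": "fever_stiff_neck", "no": "cough"},
      "emissions": {"yes": ["febrile_disease"], "no": []},
      "ask_only": true
    },
    {
      "id": "fever_stiff_neck",
      "prompt_id": "q_stiff_neck",
      "block": "fever",
      "routes": {"yes": "cough", "no": "cough"},
      "emissions": {"yes": ["severe_febrile_disease"], "no": []},
      "ask_only": true
    },
    {
      "id": "cough",
      "prompt_id": "q_cough",
      "block": "respiratory",
      "routes": {"yes": "rti_breathing_inability", "no": "diarrhoea"},
      "emissions": {"yes": [], "no": []},
      "ask_only": true
    },
    {
      "id": "rti_breathing_inability",
      "prompt_id": "q_breathing_inability",
      "block": "respiratory",
      "routes": {"yes": "diarrhoea", "no": "rti_noisy_breathing"},
      "emissions": {"yes": ["severe_rti"], "no": []},
      "ask_only": true
    },
    {
      "id": "rti_noisy_breathing",
      "prompt_id": "q_noisy_breathing",
      "block": "respiratory",
      "routes": {"yes": "diarrhoea", "no": "rti_fast_breathing"},
      "emissions": {"yes": ["severe_rti"], "no": []},
      "ask_only": true
    },
    {
      "id": "rti_fast_breathing",
      "prompt_id": "q_fast_breathing",
      "block": "respiratory",
      "routes": {"yes": "diarrhoea", "no": "diarrhoea"},
      "emissions": {"yes": ["moderate_rti"], "no": ["mild_rti"]},
      "ask_only": true
    },
    {
      "id": "diarrhoea",
      "prompt_id": "q_diarrhoea",
      "block": "gastrointestinal",
      "routes": {"yes": "gi_blood_stool", "no": "vomiting_screen"},
      "emissions": {"yes": [], "no": []},
      "ask_only": true
    },
    {
      "id": "gi_blood_stool",
      "prompt_id": "q_blood_stool",
      "block": "gastrointestinal",
      "routes": {"yes": "vomiting_gi", "no": "vomiting_gi"},
      "emissions": {"yes": ["dysentery"], "no": []},
      "ask_only": true
    },
    {
      "id": "vomiting_gi",
      "prompt_id": "q_vomiting",
      "block": "gastrointestinal",
      "routes": {"yes": "gi_lethargic", "no": "gi_lethargic"},
      "emissions": {"yes": [], "no": []},
      "ask_only": true
    },
    {
      "id": "vomiting_screen",
      "prompt_id": "q_vomiting",
      "block": "gastrointestinal",
      "routes": {"yes": "gi_lethargic", "no": "TERMINAL"},
      "emissions": {"yes": [], "no": []},
      "ask_only": true
    },
    {
      "id": "gi_lethargic",
      "prompt_id": "q_lethargic",
      "block": "gastrointestinal",
      "routes": {"yes": "TERMINAL", "no": "gi_sunken_eyes"},
      "emissions": {"yes": ["gi_severe_dehydration"], "no": []},
      "ask_only": true
    },
    {
      "id": "gi_sunken_eyes",
      "prompt_id": "q_sunken_eyes",
      "block": "gastrointestinal",
      "routes": {"yes": "TERMINAL", "no": "TERMINAL"},
      "emissions": {"yes": ["gi_some_dehydration"], "no": ["gi_no_dehydration"]},
      "ask_only": true
    }
  ],
  "assessments": [
    {
      "id": "inability_to_drink",
      "display_name": "Inability to drink or breastfeed",
      "triage": "A",
      "extra_advice": ["Offer your child small sips to drink on the way to the hospital."]
    },
    {
      "id": "neurological_emergency",
      "display_name": "Neurological emergency",
      "triage": "A",
      "extra_advice": []
    },
    {
      "id": "severe_febrile_disease",
      "display_name": "Severe febrile disease",
      "triage": "A",
      "extra_advice": ["Offer enough to drink on the way to the hospital."]
    },
    {
      "id": "febrile_disease",
      "display_name": "Febrile disease",
      "triage": "B",
      "extra_advice": ["Offer enough to drink."]
    },
    {
      "id": "severe_rti",
      "display_name": "Severe respiratory tract infection",
      "triage": "A",
      "extra_advice": []
    },
    {
      "id": "moderate_rti",
      "display_name": "Moderate respiratory tract infection",
      "triage": "B",
      "extra_advice": []
    },
    {
      "id": "mild_rti",
      "display_name": "Mild respiratory tract infection",
      "triage": "C",
      "extra_advice": ["Soothe the throat and relieve the cough with a safe home remedy."]
    },
    {
      "id": "gi_severe_dehydration",
      "display_name": "Gastrointestinal infection with severe dehydration",
      "triage": "A",
      "extra_advice": ["Offer sips of oral rehydration salt (ORS) solution on the way to the hospital."]
    },
    {
      "id": "gi_some_dehydration",
      "display_name": "Gastrointestinal infection with some dehydration",
      "triage": "B",
      "extra_advice": ["Give oral rehydration salt (ORS) solution if available."]
    },
    {
      "id": "gi_no_dehydration",
      "display_name": "Gastrointestinal infection with no dehydration",
      "triage": "C",
      "extra_advice": ["Give extra fluids and continue feeding.", "Give oral rehydration salt (ORS) solution if available."]
    },
    {
      "id": "dysentery",
      "display_name": "Dysentery",
      "triage": "B",
      "extra_advice": ["Give oral rehydration salt (ORS) solution if available."]
    }
  ]
}
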