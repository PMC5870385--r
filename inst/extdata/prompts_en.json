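{
  "locale": "en",
  "prompts": {
    "q_age": "How old is your child, in months?",
    "q_danger_drink": "Is your child unable to drink or breastfeed?",
    "q_convulsions": "Has your child had convulsions, or is your child unconscious?",
    "q_fever": "Does your child have a fever, or has the body felt hot?",
    "q_stiff_neck": "Does your child have a stiff neck?",
    "q_cough": "Does your child have a cough?",
    "q_breathing_inability": "Is breathing so difficult that your child cannot drink, talk or feed normally?",
    "q_noisy_breathing": "Do you hear a harsh noise when your child breathes while calm?",
    "q_fast_breathing": "Is your child breathing fast or with difficulty?",
    "q_diarrhoea": "Does your child have diarrhoea?",
    "q_blood_stool": "Is there blood in the stool?",
    "q_vomiting": "Is your child vomiting?",
    "q_lethargic": "Is your child unusually sleepy, or unable to drink?",
    "q_sunken_eyes": "Are your child's eyes sunken, or is your child drinking eagerly as if very thirsty?"
  },
  "answer_help": "Press 1 for yes, press 2 for no."
}
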