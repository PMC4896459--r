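{
  "version": "1.0",
  "notes": "Ten caregiver-reported yes/no ECDI items for children aged 36-59 months. Items are scored 1 (favorable) / 0 (unfavorable) after reverse coding. Only the learning/cognition and socioemotional domains feed the low-development classification (in_scope); literacy-numeracy and physical items are defined for completeness.",
  "items": [
    {"item_id": "identifies_letters",   "label": "Can identify or name at least ten letters of the alphabet",                  "domain": "literacy_numeracy",  "reverse_coded": false, "in_scope": false},
    {"item_id": "reads_words",          "label": "Can read at least four simple, popular words",                               "domain": "literacy_numeracy",  "reverse_coded": false, "in_scope": false},
    {"item_id": "knows_numbers",        "label": "Knows the name and recognizes the symbol of all numbers from 1 to 10",       "domain": "literacy_numeracy",  "reverse_coded": false, "in_scope": false},
    {"item_id": "follows_directions",   "label": "Follows simple directions on how to do something correctly",                 "domain": "learning_cognition", "reverse_coded": false, "in_scope": true},
    {"item_id": "works_independently",  "label": "When given something to do, is able to do it independently",                 "domain": "learning_cognition", "reverse_coded": false, "in_scope": true},
    {"item_id": "too_sick_to_play",     "label": "Is sometimes too sick to play",                                              "domain": "physical",           "reverse_coded": true,  "in_scope": false},
    {"item_id": "picks_up_small_object","label": "Can pick up a small object with two fingers",                                "domain": "physical",           "reverse_coded": false, "in_scope": false},
    {"item_id": "kicks_bites_hits",     "label": "Kicks, bites, or hits other children or adults",                             "domain": "socioemotional",     "reverse_coded": true,  "in_scope": true},
    {"item_id": "easily_distracted",    "label": "Gets easily distracted",                                                     "domain": "socioemotional",     "reverse_coded": true,  "in_scope": true},
    {"item_id": "gets_along",           "label": "Gets along well with other children",                                        "domain": "socioemotional",     "reverse_coded": false, "in_scope": true}
  ]
}
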