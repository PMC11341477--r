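"pt","soc"
"NAUSEA","Gastrointestinal disorders"
"FATIGUE","General disorders and administration site conditions"
"HEADACHE","Nervous system disorders"
"DIARRHOEA","Gastrointestinal disorders"
"MUSCLE SPASMS","Musculoskeletal and connective tissue disorders"
"DIZZINESS","Nervous system disorders"
"RASH","Skin and subcutaneous tissue disorders"
"VOMITING","Gastrointestinal disorders"
"TINNITUS","Ear and labyrinth disorders"
"PAIN","General disorders and administration site conditions"
"ALOPECIA","Skin and subcutaneous tissue disorders"
"DEAFNESS","Ear and labyrinth disorders"
"BLOOD GLUCOSE INCREASED","Investigations"
"ARTHRALGIA","Musculoskeletal and connective tissue disorders"
"PRURITUS","Skin and subcutaneous tissue disorders"
"DYSPNOEA","Respiratory, thoracic and mediastinal disorders"
"ASTHENIA","General disorders and administration site conditions"
"HYPOACUSIS","Ear and labyrinth disorders"
"INFUSION RELATED REACTION","Injury, poisoning and procedural complications"
"MYALGIA","Musculoskeletal and connective tissue disorders"
"ANXIETY","Psychiatric disorders"
"WEIGHT DECREASED","Investigations"
"VISION BLURRED","Eye disorders"
"DRY SKIN","Skin and subcutaneous tissue disorders"
"HYPERGLYCAEMIA","Metabolism and nutrition disorders"
"INSOMNIA","Psychiatric disorders"
"EAR DISCOMFORT","Ear and labyrinth disorders"
"DYSGEUSIA","Nervous system disorders"
"ABDOMINAL PAIN","Gastrointestinal disorders"
"AMENORRHOEA","Reproductive system and breast disorders"
"DIPLOPIA","Eye disorders"
"BLOOD PRESSURE INCREASED","Investigations"
"CONDITION AGGRAVATED","General disorders and administration site conditions"
"EYE PAIN","Eye disorders"
"DECREASED APPETITE","Metabolism and nutrition disorders"
"CHEST DISCOMFORT","General disorders and administration site conditions"
"OTOTOXICITY","Ear and labyrinth disorders"
"GLYCOSYLATED HAEMOGLOBIN INCREASED","Investigations"
"EYE SWELLING","Eye disorders"
"POLYDIPSIA","Metabolism and nutrition disorders"
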