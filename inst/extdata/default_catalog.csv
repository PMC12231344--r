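category,klass,members
Organic mental disorders,mental,F00-F09
Mental and behavioral disorders due to psychoactive substance use,mental,F10-F19
Schizophrenia and delusional diseases,mental,F20;F22;F24;F25;F28
Depression and mood diseases,mental,F30-F34;F38;F39
Neurotic stress-related and somatoform diseases,mental,F40-F45;F48
Eating disorders,mental,F50
Sleep disorders_F,mental,F51.0-F51.3
Specific personality disorders,mental,F60
Mental retardation,mental,F70-F79
Pervasive developmental disorders,mental,F84
Behavioral and emotional disorders with onset usually occurring in childhood and adolescence,mental,F90-F98
Heart failure,physical,I50.9
Ischemic heart disease,physical,I25.1
Hypertension,physical,I10
Prostate diseases,physical,N40
"Esophagus, stomach, and duodenum diseases",physical,K29.5
Diabetes,physical,E11.9
Cerebrovascular disease,physical,I67.2;I69.3;I63.9
Dyslipidemia,physical,E78.5
Anemia,physical,D64.9
Other metabolic diseases,physical,E77.8
Dorsopathies,physical,
Other cardiovascular diseases,physical,
Other respiratory diseases,physical,
Chronic obstructive pulmonary disease,physical,
Emphysema chronic bronchitis,physical,
Dementia,physical,
Other genitourinary diseases,physical,
Other musculoskeletal and joint diseases,physical,
Other neurological diseases,physical,
"Ear, nose, and throat diseases",physical,
Cardiac valve diseases,physical,
Osteoporosis,physical,
"Chronic pancreas, biliary tract, and gall bladder disease",physical,
Sleep disorders,physical,
Solid neoplasms,physical,
Osteoarthritis and other degenerative joint diseases,physical,
Inflammatory arthropathies,physical,
Epilepsy,physical,
Cataract and other lens diseases,physical,
Colitis and related diseases,physical,
Thyroid diseases,physical,
Chronic liver diseases,physical,
Atrial fibrillation,physical,
Chronic ulcer of the skin,physical,
Chronic infectious diseases,physical,
Parkinson and parkinsonism,physical,
Migraine and facial pain syndromes,physical,
Blood and blood-forming organ diseases,physical,
Chronic kidney diseases,physical,
Allergy,physical,
Peripheral neuropathy,physical,
Other eye diseases,physical,
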