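# Discharge-summary section headers recognized by detect_sections().
# A header line is the name below followed by a colon.
ADMISSION DIAGNOSIS
DISCHARGE DIAGNOSIS
HISTORY OF PRESENT ILLNESS
PAST MEDICAL HISTORY
MEDICATIONS
MEDICATIONS ON ADMISSION
MEDICATIONS ON DISCHARGE
ALLERGIES
PHYSICAL EXAMINATION
LABORATORY DATA
HOSPITAL COURSE
BRIEF HOSPITAL COURSE
ASSESSMENT AND PLAN
DISCHARGE INSTRUCTIONS
FOLLOW-UP
SOCIAL HISTORY
FAMILY HISTORY
REVIEW OF SYSTEMS
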