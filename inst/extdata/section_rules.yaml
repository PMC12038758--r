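# Default section header rules. A header with require_colon: true matches a
# line-initial phrase followed by a colon; require_colon: false lets the
# phrase open a section anywhere in the running text (this reproduces the
# documented behaviour where "Goals of Care:" opens an excluded section that
# an in-line "outcome measures" phrase immediately re-opens for inclusion).
# The last header seen before a span governs its disposition.
rules:
  - {label: subjective,        pattern: Subjective,            disposition: include}
  - {label: history,           pattern: History,               disposition: include}
  - {label: chief_complaint,   pattern: Chief Complaint,       disposition: include}
  - {label: objective,         pattern: Objective,             disposition: include}
  - {label: examination,       pattern: Examination,           disposition: include}
  - {label: assessment,        pattern: Assessment,            disposition: include}
  - {label: plan,              pattern: Plan,                  disposition: include}
  - {label: treatment,         pattern: Treatment,             disposition: include}
  - {label: outcome_measures,  pattern: outcome measures,      disposition: include,
     require_colon: false}
  - {label: medications,       pattern: Medications,           disposition: exclude}
  - {label: medications,       pattern: Current Medications,   disposition: exclude}
  - {label: abbreviations,     pattern: Abbreviations,         disposition: exclude}
  - {label: abbreviations,     pattern: Abbreviation Legend,   disposition: exclude}
  - {label: goals_of_care,     pattern: Goals of Care,         disposition: exclude}
  - {label: patient_education, pattern: Patient Education,     disposition: exclude}
  - {label: patient_education, pattern: Patient Instructions,  disposition: exclude}
  - {label: template,          pattern: Template,              disposition: exclude}
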