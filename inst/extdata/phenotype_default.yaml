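# Editable phenotyping configuration: code sets and lab thresholds.
# Diagnosis sets are ICD-9-CM prefix sets; medication sets are NDC package
# codes (deployment-specific; supply your own ingredient-to-NDC rollup).
depression_dx: ["296.2", "296.3", "298.0", "300.4", "309.1", "311"]
family_history: ["V18.0"]
glucose_loinc: ["1558-6", "2339-0", "2345-7"]
hba1c_loinc: ["4548-4", "17856-6", "4549-2", "17855-8"]
lab_order_cpt: ["82947", "80047", "80048", "80053", "80069", "83036"]
t2d_meds: ["00093-1048-01", "00093-7214-01", "00378-0221-01"]
insulin_meds: ["00002-8215-01", "00088-2219-01"]
window_years: 4
min_visits: 2
abnormal_fasting_glucose: 126
abnormal_random_glucose: 200
abnormal_hba1c: 6.5
normal_fasting_glucose: 110
normal_random_glucose: 140
normal_hba1c: 6.0
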