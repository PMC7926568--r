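cadres:
- cadre_id: midwife
  baseline_stock: 12828.0
  attrition_rate: 0.035
  participation_rate: 0.93
  awt:
    possible_working_days: 260.0
    public_holidays: 9.0
    annual_leave: 21.0
    sick_leave: 5.0
    other_absences: 4.0
    hours_per_day: 8.0
  support_activities:
  - name: handing_over
    sas: 0.125
  - name: clinical_meetings
    sas: 0.05
  pipeline:
    enrolment_by_year:
      '2018': 2600.0
      '2019': 2704.0
      '2020': 2812.0
      '2021': 2925.0
      '2022': 3042.0
      '2023': 3163.0
      '2024': 3290.0
      '2025': 3421.0
      '2026': 3558.0
      '2027': 3701.0
    dropout_rate: 0.08
    training_duration: 3
    pass_rate: 0.88
    immigration_by_year:
      '2021': 15.0
      '2022': 15.0
      '2023': 15.0
      '2024': 15.0
      '2025': 15.0
      '2026': 15.0
      '2027': 15.0
      '2028': 15.0
      '2029': 15.0
      '2030': 15.0
  baseline_income: 10750.0
  income_inflation: 0.08
- cadre_id: obstetrician_gynaecologist
  baseline_stock: 189.0
  attrition_rate: 0.02
  participation_rate: 1.0
  awt:
    possible_working_days: 260.0
    public_holidays: 9.0
    annual_leave: 28.0
    sick_leave: 5.0
    other_absences: 4.0
    hours_per_day: 8.0
  support_activities:
  - name: clinical_meetings
    sas: 0.15
  pipeline:
    enrolment_by_year:
      '2017': 34.0
      '2018': 36.0
      '2019': 37.0
      '2020': 39.0
      '2021': 41.0
      '2022': 43.0
      '2023': 46.0
      '2024': 48.0
      '2025': 50.0
      '2026': 53.0
    dropout_rate: 0.05
    training_duration: 4
    pass_rate: 0.92
    immigration_by_year:
      '2021': 2.0
      '2022': 2.0
      '2023': 2.0
      '2024': 2.0
      '2025': 2.0
      '2026': 2.0
      '2027': 2.0
      '2028': 2.0
      '2029': 2.0
      '2030': 2.0
  baseline_income: 18300.0
  income_inflation: 0.08
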