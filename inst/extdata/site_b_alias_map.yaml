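- code: transport
  unified: transportation
- code: transport_no_vehicle
  parent: transport
  unified: transportation
- code: transport_cost
  parent: transport
- code: language
  unified: language_interpreter
- code: language_interpreter_needed
  parent: language
  unified: language_interpreter
- code: language_forms
  parent: language
- code: finance
  unified: financial_problems
- code: finance_copay
  parent: finance
- code: finance_income_loss
  parent: finance
  unified: financial_problems
- code: insurance
  unified: insurance_uninsured
- code: insurance_lapsed
  parent: insurance
  unified: insurance_uninsured
- code: insurance_underinsured
  parent: insurance
- code: support
  unified: social_practical_support
- code: support_no_family_near
  parent: support
- code: childcare
  unified: childcare_issues
- code: eldercare
  unified: adult_care_issues
- code: fear_anxiety
  unified: fear
- code: scheduling
  unified: system_problems_scheduling
- code: scheduling_work
  parent: scheduling
  unified: work_schedule_conflicts
- code: beliefs
  unified: perceptions_beliefs_tests_treatment
- code: case_management
- code: none
  unified: none
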