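{
  "scenario_name": "rsv_vaccine_safety",
  "picos": {
    "population": "individuals who received the RSV vaccine",
    "intervention": "administration of the RSV vaccine",
    "comparison": null,
    "outcomes": "safety-related outcomes, such as local adverse events at the injection site, systemic adverse events, and serious adverse events",
    "study_design": "experimental and observational studies"
  },
  "reasons": {
    "intervention_comparator": "Unrelated to RSV vaccine",
    "population": "Research subjects are not RSV vaccine recipients",
    "outcome": "Not a safety study of RSV vaccine",
    "study_design": "Not an experimental or observational study of RSV vaccine"
  },
  "definitions": {
    "intervention_comparator": "An RSV vaccine is an active immunization product against respiratory syncytial virus. Passive immunoprophylaxis products such as monoclonal antibodies (e.g. palivizumab) or RSV-specific immunoglobulins are not vaccines.",
    "outcome": "Safety-related outcomes include local adverse events at the injection site, systemic adverse events, and serious adverse events. Protection or efficacy endpoints alone are not safety outcomes.",
    "study_design": "Clinical research generally refers to research conducted on human subjects to assess vaccine safety and efficacy; experimental designs include randomized controlled trials, observational designs include cohort and case-control studies."
  }
}
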