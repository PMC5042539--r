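{
  "meta": {
    "description": "Default calibrated parameter fixture for the ketone monoester absorption model",
    "units": "amounts mmol, time h, volumes L"
  },
  "parameters": {
    "name": ["body_weight_kg", "blood_volume_L", "liver_volume_L", "ester_molar_mass_g_mol", "lloq_mM", "gut.upper_proximal.transit_k", "gut.upper_proximal.hydrolysis_k", "gut.upper_proximal.passive_k.ester", "gut.upper_proximal.passive_k.butanediol", "gut.upper_proximal.passive_k.bhb", "gut.lower_proximal.transit_k", "gut.lower_proximal.hydrolysis_k", "gut.lower_proximal.passive_k.ester", "gut.lower_proximal.passive_k.butanediol", "gut.lower_proximal.passive_k.bhb", "gut.upper_distal.transit_k", "gut.upper_distal.hydrolysis_k", "gut.upper_distal.passive_k.ester", "gut.upper_distal.passive_k.butanediol", "gut.upper_distal.passive_k.bhb", "gut.lower_distal.transit_k", "gut.lower_distal.hydrolysis_k", "gut.lower_distal.passive_k.ester", "gut.lower_distal.passive_k.butanediol", "gut.lower_distal.passive_k.bhb", "gut.lower_proximal.mct1.vmax", "gut.lower_proximal.mct1.km", "gut.lower_proximal.smct1.vmax", "gut.lower_proximal.smct1.km", "gut.lower_proximal.mct4.vmax", "gut.lower_proximal.mct4.km", "gut.upper_distal.mct1.vmax", "gut.upper_distal.mct1.km", "gut.upper_distal.smct1.vmax", "gut.upper_distal.smct1.km", "gut.upper_distal.mct4.vmax", "gut.upper_distal.mct4.km", "gut.lower_distal.mct1.vmax", "gut.lower_distal.mct1.km", "gut.lower_distal.smct1.vmax", "gut.lower_distal.smct1.km", "gut.lower_distal.mct4.vmax", "gut.lower_distal.mct4.km", "portal.outflow_k", "liver.ester_hydrolysis_k", "liver.butanediol_to_bhb_k", "liver.bhb_to_acac_k", "liver.acac_to_bhb_k", "liver.acac_to_acetone_k", "liver.endogenous.base_rate", "liver.endogenous.imax", "liver.endogenous.ic50", "liver.endogenous.w_bhb", "liver.endogenous.w_acac", "liver.endogenous.w_other", "liver.mct1_bhb_out.vmax", "liver.mct1_bhb_out.km", "liver.mct1_bhb_in.vmax", "liver.mct1_bhb_in.km", "liver.mct1_acac_out.vmax", "liver.mct1_acac_out.km", "liver.mct1_acac_in.vmax", "liver.mct1_acac_in.km", "liver.passive.ester.out", "liver.passive.ester.in", "liver.passive.butanediol.out", "liver.passive.butanediol.in", "liver.passive.acetone.out", "liver.passive.acetone.in", "blood.ester_hydrolysis_k", "blood.butanediol_to_bhb_k", "blood.acac_to_acetone_k", "blood.other.production_rate", "blood.other.loss_k", "tissues.mct1_bhb_in.vmax", "tissues.mct1_bhb_in.km", "tissues.mct1_bhb_out.vmax", "tissues.mct1_bhb_out.km", "tissues.mct2_bhb_in.vmax", "tissues.mct2_bhb_in.km", "tissues.mct2_bhb_out.vmax", "tissues.mct2_bhb_out.km", "tissues.mct1_acac_in.vmax", "tissues.mct1_acac_in.km", "tissues.mct1_acac_out.vmax", "tissues.mct1_acac_out.km", "tissues.mct2_acac_in.vmax", "tissues.mct2_acac_in.km", "tissues.mct2_acac_out.vmax", "tissues.mct2_acac_out.km", "tissues.passive.ester.in", "tissues.passive.ester.out", "tissues.passive.butanediol.in", "tissues.passive.butanediol.out", "tissues.passive.acetone.in", "tissues.passive.acetone.out", "tissues.bhb_consumption_k", "tissues.acac_consumption_k", "tissues.bhb_renal_k", "tissues.acac_renal_k", "tissues.acetone_exhalation_k"],
    "value": [70, 5, 1.8, 176.212, 0.02, 2.5, 1, 2.5, 2.5, 2.5, 1.5, 1.2, 0.1, 0.1, 0.1, 1, 1.2, 0.15, 0.15, 0.15, 0.35, 1, 0.1, 0.1, 0.1, 20, 300, 0.3, 1, 48, 300, 200, 300, 1.5, 1, 480, 300, 240, 300, 2, 1, 580, 300, 6, 1.5, 1, 0.25, 1, 0.08, 6, 0.8, 8, 1, 1, 1, 150, 20, 60, 20, 100, 20, 40, 20, 0.5, 0.5, 0.5, 0.5, 1, 1, 0.4, 0.6, 0.03, 5, 0.5, 140, 20, 25, 10, 1, 0.8, 1, 0.8, 30, 10, 15, 10, 3, 0.8, 1.5, 0.8, 0.3, 0.3, 0.3, 0.3, 1, 1, 3, 3, 0.02, 0.02, 2],
    "unit": ["kg", "L", "L", "g/mol", "mM", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "mmol/h", "", "mmol", "", "", "", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "mmol/h", "1/h", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "mmol/h", "mmol", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h", "1/h"],
    "provenance": ["literature", "literature", "literature", "literature", "fixture-default", "literature", "estimated", "estimated", "estimated", "estimated", "literature", "estimated", "estimated", "estimated", "estimated", "literature", "estimated", "estimated", "estimated", "estimated", "literature", "estimated", "estimated", "estimated", "estimated", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "literature", "estimated", "estimated", "estimated", "estimated", "literature", "estimated", "estimated", "estimated", "fixture-default", "fixture-default", "fixture-default", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "estimated", "estimated", "estimated", "estimated", "estimated", "estimated", "estimated", "estimated", "literature", "estimated", "estimated", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "scaled", "literature", "estimated", "estimated", "estimated", "estimated", "estimated", "estimated", "estimated", "estimated", "literature", "literature", "literature"]
  }
}
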