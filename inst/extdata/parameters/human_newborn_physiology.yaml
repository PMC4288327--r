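schema_version: 1
species: human
life_stage: newborn
description: >
  Newborn human (3.5 kg) physiology and chemical properties used when the
  calibrated postnatal-day-5 monkey model is extrapolated to newborn humans.
physiology:
  body_weight: 3.5
  cardiac_output: 35.8
  venous_blood_fraction: 0.6666666666666666
  bile_flow: 0.002
  glomerular_filtration: 0.24
  tissue_volumes:
    blood: 0.28
    liver: 0.14
    fat: 0.35
    richly_perfused: 0.25
    slowly_perfused: 1.75
    enterocyte: 0.035
    gut_lumen: 0.05
  tissue_flows:
    liver_arterial: 2.327
    gut: 6.623
    fat: 1.8616
    richly_perfused: 15.752
    slowly_perfused: 9.2364
chemical:
  molecular_weight_parent: 228.29
  molecular_weight_conjugate: 404.39
  log_kow: 3.3
  blood_serum_ratio: 1.0
  partition_coefficients:
    liver: 1.5
    fat: 3.3
    richly_perfused: 1.5
    slowly_perfused: 1.0
provenance:
  physiology:
    body_weight: assumed (term newborn)
    cardiac_output: assumed (allometric, 14 L/h per kg^0.75)
    venous_blood_fraction: assumed (2/3 venous, 1/3 arterial)
    bile_flow: assumed (informational)
    glomerular_filtration: assumed (informational)
    tissue_volumes:
      blood: assumed (reference compilation)
      liver: assumed (reference compilation)
      fat: assumed (reference compilation)
      richly_perfused: assumed (lumped well-perfused viscera)
      slowly_perfused: assumed (lumped muscle/skin/bone)
      enterocyte: assumed (gut-wall epithelium)
      gut_lumen: assumed (capacity only)
    tissue_flows:
      liver_arterial: assumed (reference fraction of cardiac output)
      gut: assumed (splanchnic flow, reference fraction)
      fat: assumed (reference fraction)
      richly_perfused: assumed (balance of cardiac output)
      slowly_perfused: assumed (reference fraction)
  chemical:
    molecular_weight_parent: paper-cited (unlabelled BPA)
    molecular_weight_conjugate: assumed (BPA glucuronide)
    log_kow: paper-cited
    blood_serum_ratio: assumed
    partition_coefficients:
      liver: assumed
      fat: paper-cited (human value, 3.3)
      richly_perfused: assumed
      slowly_perfused: assumed
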