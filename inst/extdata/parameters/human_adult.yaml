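schema_version: 1
species: human
life_stage: adult
description: >
  Adult human (70 kg). Structure carried over from the calibrated adult
  monkey model with human physiology: first-order hepatic and enterocyte
  conjugation (rate constants rescaled by the body-weight ratio to the
  -0.25 power), no biliary excretion, and a one-compartment conjugate model
  excreted in urine with renal reabsorption removed.
physiology:
  body_weight: 70.0
  cardiac_output: 338.8
  venous_blood_fraction: 0.6666666666666666
  bile_flow: 0.03
  glomerular_filtration: 7.5
  tissue_volumes:
    blood: 5.2
    liver: 1.8
    fat: 13.0
    richly_perfused: 5.0
    slowly_perfused: 35.0
    enterocyte: 0.7
    gut_lumen: 1.0
  tissue_flows:
    liver_arterial: 22.022
    gut: 62.678
    fat: 17.6176
    richly_perfused: 149.072
    slowly_perfused: 87.4104
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
metabolism:
  hepatic_mode: first_order
  k_hepatic: 155.0923
  k_gut_metabolism: 6.20369
  k_enterocyte_conjugate_efflux: 2.58487
absorption:
  k_gastric_emptying: 1.292436
  k_lumen_uptake: 0.775461
  k_portal_transfer: 1.033947
conjugate:
  n_compartments: 1
  volumes:
    central: 14.0
  urinary_clearance: 10.8557
  fecal_clearance: 0.0
provenance:
  physiology:
    body_weight: assumed (standard reference adult human)
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
      fat: paper-cited (vial equilibration with human tissue, 3.3)
      richly_perfused: assumed
      slowly_perfused: assumed
  metabolism:
    hepatic_mode: paper-cited (carried over from the monkey model)
    k_hepatic: extrapolated (monkey value scaled by (BW ratio)^-0.25)
    k_gut_metabolism: extrapolated (scaled first-order gut term from monkeys)
    k_enterocyte_conjugate_efflux: extrapolated (scaled from monkey)
  absorption:
    k_gastric_emptying: extrapolated (scaled from monkey)
    k_lumen_uptake: extrapolated (scaled from monkey)
    k_portal_transfer: extrapolated (scaled from monkey)
  conjugate:
    n_compartments: paper-cited (one compartment, as in monkey)
    volumes:
      central: assumed (extracellular-water scale)
    urinary_clearance: extrapolated (monkey value scaled by BW^0.75)
    fecal_clearance: assumed (predominantly urinary excretion, no biliary route)
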