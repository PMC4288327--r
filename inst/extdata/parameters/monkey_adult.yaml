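schema_version: 1
species: monkey
life_stage: adult
description: >
  Adult monkey (5 kg). Flow-limited parent-compound PBPK model with
  first-order hepatic conjugation, first-order enterocyte conjugation with
  active basolateral efflux of conjugate to systemic blood, no biliary
  excretion, and a one-compartment systemic conjugate model with
  capacity-limited (Michaelis-Menten) renal reabsorption slowing urinary
  elimination.
physiology:
  body_weight: 5.0
  cardiac_output: 46.8
  venous_blood_fraction: 0.6666666666666666
  bile_flow: 0.008
  glomerular_filtration: 0.6
  tissue_volumes:
    blood: 0.37
    liver: 0.15
    fat: 0.5
    richly_perfused: 0.25
    slowly_perfused: 2.5
    enterocyte: 0.05
    gut_lumen: 0.1
  tissue_flows:
    liver_arterial: 0.936
    gut: 7.02
    fat: 2.34
    richly_perfused: 22.932
    slowly_perfused: 13.572
chemical:
  molecular_weight_parent: 234.33
  molecular_weight_conjugate: 410.46
  log_kow: 3.3
  blood_serum_ratio: 1.0
  partition_coefficients:
    liver: 1.5
    fat: 5.0
    richly_perfused: 1.5
    slowly_perfused: 1.0
metabolism:
  hepatic_mode: first_order
  k_hepatic: 300.0
  k_gut_metabolism: 12.0
  k_enterocyte_conjugate_efflux: 5.0
absorption:
  k_gastric_emptying: 2.5
  k_lumen_uptake: 1.5
  k_portal_transfer: 2.0
conjugate:
  n_compartments: 1
  volumes:
    central: 1.0
  urinary_clearance: 1.5
  fecal_clearance: 0.002
  renal_reabsorption:
    vmax: 3500.0
    km: 2500.0
provenance:
  physiology:
    body_weight: assumed (standard reference adult monkey)
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
      gut: assumed (portal flow, reference fraction)
      fat: assumed (reference fraction)
      richly_perfused: assumed (balance of cardiac output)
      slowly_perfused: assumed (reference fraction)
  chemical:
    molecular_weight_parent: paper-cited (deuterated BPA)
    molecular_weight_conjugate: assumed (BPA glucuronide, d6)
    log_kow: paper-cited
    blood_serum_ratio: assumed
    partition_coefficients:
      liver: assumed
      fat: assumed (animal value, as in rat)
      richly_perfused: assumed
      slowly_perfused: assumed
  metabolism:
    hepatic_mode: paper-cited (first-order constant fitted to i.v. serum data)
    k_hepatic: calibrated (high hepatic extraction)
    k_gut_metabolism: calibrated (visually fitted oral serum profiles)
    k_enterocyte_conjugate_efflux: calibrated (rapid conjugate peak)
  absorption:
    k_gastric_emptying: calibrated (aqueous gavage)
    k_lumen_uptake: calibrated
    k_portal_transfer: calibrated (unconjugated escape from enterocyte)
  conjugate:
    n_compartments: paper-cited (one compartment for monkey conjugates)
    volumes:
      central: assumed (extracellular-water scale)
    urinary_clearance: calibrated (74-82% urinary recovery)
    fecal_clearance: calibrated (<3% fecal recovery)
    renal_reabsorption:
      vmax: calibrated (fitted to slowed conjugate clearance)
      km: assumed (affinity of MRP2 toward bilirubin glucuronides)
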