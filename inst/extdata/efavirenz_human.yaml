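# Efavirenz, human parameter set.
# Units as in efavirenz_rat.yaml.
name: efavirenz
mw: 315.67
logp: 4.6
pka: 10.2
pka_type: acid
diff_coeff: 0.7473e-5
density: 1.395
sol_aq: 0.009
sol_aq_ph: 6.97
sol_fassif: 0.182
sol_fessif: 0.847
bile_fassif_mM: 3.0
bile_fessif_mM: 15.0
solubilization_factor: 4342.8
bile_sr: 3.57e5
bile_sr_ref: 3.57e5
interfacial_tension: 0.02327
nano_factor: 1.381
nano_radius_um: 1.0
fup_percent: 0.22
bp_ratio: 0.74
peff: 7.385e-4
kaff: 0.0755
enzymes:
  - enzyme: CYP2B6
    site: liver
    vmax_mg_s: 0.05
    km_mg_l: 3.914
  - enzyme: CYP3A4
    site: liver
    vmax_mg_s: 0.00083
    km_mg_l: 6.314
  - enzyme: CYP3A4
    site: gut
    vmax_mg_s: 0.00044
    km_mg_l: 6.314
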