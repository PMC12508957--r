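# Efavirenz, rat parameter set.
# Units: mw g/mol; diff_coeff cm2/s; density g/mL; solubilities mg/mL;
# interfacial_tension J/m2; peff cm/s; enzyme vmax mg/s (whole organ), km mg/L.
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
fup_percent: 0.58
bp_ratio: 0.92
peff: 1.658e-4
kaff: 0.0755
enzymes:
  - enzyme: CYP2B2
    site: liver
    vmax_mg_s: 0.0517
    km_mg_l: 0.9035
  - enzyme: CYP3A9
    site: liver
    vmax_mg_s: 0.0318
    km_mg_l: 0.9278
  - enzyme: CYP3A9
    site: gut
    vmax_mg_s: 0.00044
    km_mg_l: 0.9278
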