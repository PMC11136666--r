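# Synthetic ground truth: 5 animals per group, fasted-mouse rates
# (nmol/g/min), pool sizes in nmol/g.
n_animals: 5
groups: [A]
ra_glycerol: 30
ra_palmitate: 15
ra_co2: 1500
frac_oxidized: 0.30
tca_fractions:
  liver: 0.60
  gastrocnemius: 0.20
  soleus: 0.35
  diaphragm: 0.45
pool_sizes:
  glycerol: 80
  palmitate: 60
  co2: 1000
between_animal_cv: 0.10
noise_cv: 0.05
seed: 1
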