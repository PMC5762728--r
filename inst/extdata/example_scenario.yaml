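# Example pipeline scenario: the rat metal-binding-domain analog digested by
# the ACE N-domain, sampled over an hour, with the 18O-standard quantitation
# of the 1-13 product.
substrate: Ac-ratAbeta1-16-amide
enzyme: N-ACE
rates:
  '13': 0.05     # 1/min, first-order rate at the Arg13-His14 bond
times: [10, 20, 40, 60]
c0: 20           # uM substrate
standard_conc: 10
tol: 0.3
seed: 17
spectrum:
  noise_cv: 0.05
  suppression_cutoff: 500
labeling:
  n_sites: 2
  p_inc: 0.95
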