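regions:
- name: epsilon_prime
  state: 1
  phi_lo: -180.0
  phi_hi: -20.0
  psi_lo: -180.0
  psi_hi: -140.0
- name: epsilon
  state: 2
  phi_lo: 20.0
  phi_hi: 180.0
  psi_lo: 140.0
  psi_hi: 180.0
- name: epsilon
  state: 2
  phi_lo: 20.0
  phi_hi: 180.0
  psi_lo: -180.0
  psi_hi: -140.0
- name: alpha_R
  state: 3
  phi_lo: -160.0
  phi_hi: -20.0
  psi_lo: -70.0
  psi_hi: -10.0
- name: gamma
  state: 4
  phi_lo: 40.0
  phi_hi: 110.0
  psi_lo: -100.0
  psi_hi: -60.0
- name: delta_R
  state: 5
  phi_lo: -160.0
  phi_hi: -20.0
  psi_lo: -10.0
  psi_hi: 60.0
- name: delta_L
  state: 6
  phi_lo: 20.0
  phi_hi: 160.0
  psi_lo: -60.0
  psi_hi: 10.0
- name: zeta
  state: 7
  phi_lo: -180.0
  phi_hi: -110.0
  psi_lo: 60.0
  psi_hi: 100.0
- name: gamma_prime
  state: 8
  phi_lo: -110.0
  phi_hi: -40.0
  psi_lo: 60.0
  psi_hi: 100.0
- name: alpha_L
  state: 9
  phi_lo: 20.0
  phi_hi: 160.0
  psi_lo: 10.0
  psi_hi: 70.0
- name: beta_s
  state: 10
  phi_lo: -180.0
  phi_hi: -110.0
  psi_lo: 100.0
  psi_hi: 180.0
- name: beta_p
  state: 11
  phi_lo: -110.0
  phi_hi: -40.0
  psi_lo: 100.0
  psi_hi: 180.0
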