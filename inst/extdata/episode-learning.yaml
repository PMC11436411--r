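# Episodic 2D training configuration (the standard study conditions):
# kappa0 = 0.03/um grid centre with 0.006/um increments, 0.5 s learning steps
# at 120 um/s, point source of strength 10 pM at the origin, swimmer starting
# 509 um away.
v: 120
dt_learn: 0.5
n_sub: 1
c0: 10
egg_center: [0, 0, 0]
x0: [360, -360, 0]
kappa0: 0.03
tau0: 0.006
d_kappa: 0.006
d_tau: 0.004
X: 50
alpha: 1
gamma: 0.8
epsilon: 0.1
dim: 2
episodes: 10
steps: 50000
seed: 1
noise:
  enabled: false
  lambda: 10
  sigma_kappa: 0.005
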