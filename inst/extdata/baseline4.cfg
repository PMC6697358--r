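[network]
n_units = 4
h_mode = dynamic

[shared]
C = 20
E_Na = 50
E_K = -85
E_synE = 0
E_synI = -75
theta_h = -48
sigma_h = 8
theta_m = -37
sigma_m = -6
theta_n = -29
sigma_n = -4
epsilon = 4000
g_synE = 10
g_synI = 60

[unit 1]
name = pre-I
excitatory = TRUE
g_NaP = 4.5
g_K = 1
g_L = 3
E_L = -65
theta_out = -32
sigma_out = -8

[unit 2]
name = early-I
excitatory = FALSE
g_NaP = 0.25
g_K = 10
g_L = 3.25
E_L = -60
theta_out = -30
sigma_out = -4
tau_p = 2000
d_adapt = 1

[unit 3]
name = post-I
excitatory = FALSE
g_NaP = 0.25
g_K = 10
g_L = 3.25
E_L = -60
theta_out = -30
sigma_out = -4
tau_p = 1500
d_adapt = 1

[unit 4]
name = aug-E
excitatory = FALSE
g_NaP = 0.25
g_K = 10
g_L = 3.25
E_L = -60
theta_out = -30
sigma_out = -4
tau_p = 2000
d_adapt = 1

[weights]
a12 = 0.59999999999999998
b23 = 0.59999999999999998
b24 = 0.29999999999999999
b31 = 0.125
b32 = 0.27000000000000002
b34 = 0.45000000000000001
b41 = 0.014999999999999999
b42 = 0.29999999999999999
b43 = 0.050000000000000003

[drives]
c1 = -0.029999999999999999 0.19 0.57999999999999996 0.20000000000000001
c2 = 0.095000000000000001 0.29999999999999999 0 0.40000000000000002
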