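pressure_bar,temperature_K,reaction,isotope,k_obs,k_err
1,298.15,hydride,H,2.26e6,0.21e6
250,298.15,hydride,H,2.11e6,0.18e6
500,298.15,hydride,H,2.12e6,0.17e6
750,298.15,hydride,H,2.05e6,0.12e6
1000,298.15,hydride,H,2.01e6,0.20e6
1250,298.15,hydride,H,1.80e6,0.12e6
1500,298.15,hydride,H,1.99e6,0.25e6
1750,298.15,hydride,H,1.85e6,0.20e6
2000,298.15,hydride,H,2.02e6,0.15e6
1,298.15,hydride,D,1.01e6,0.12e6
250,298.15,hydride,D,1.03e6,0.13e6
500,298.15,hydride,D,0.99e6,0.17e6
750,298.15,hydride,D,0.99e6,0.12e6
1000,298.15,hydride,D,1.02e6,0.06e6
1250,298.15,hydride,D,1.11e6,0.21e6
1500,298.15,hydride,D,1.14e6,0.17e6
1750,298.15,hydride,D,1.29e6,0.26e6
2000,298.15,hydride,D,1.56e6,0.31e6
1,298.15,proton,H,2.39e4,0.18e4
250,298.15,proton,H,2.31e4,0.23e4
500,298.15,proton,H,2.11e4,0.21e4
750,298.15,proton,H,2.10e4,0.10e4
1000,298.15,proton,H,2.02e4,0.08e4
1250,298.15,proton,H,1.89e4,0.09e4
1500,298.15,proton,H,1.71e4,0.12e4
1750,298.15,proton,H,1.55e4,0.17e4
2000,298.15,proton,H,1.36e4,0.26e4
1,298.15,proton,D,1.10e4,0.05e4
250,298.15,proton,D,0.96e4,0.08e4
500,298.15,proton,D,0.93e4,0.07e4
750,298.15,proton,D,0.91e4,0.14e4
1000,298.15,proton,D,0.90e4,0.11e4
1250,298.15,proton,D,0.86e4,0.11e4
1500,298.15,proton,D,0.81e4,0.09e4
1750,298.15,proton,D,0.83e4,0.10e4
2000,298.15,proton,D,0.99e4,0.12e4
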