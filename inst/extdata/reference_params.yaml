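# Reference parameter set of the dryland community model.
# Units: rates 1/y or m^2/(kg y); biomass/water kg/m^2; P mm/y.
Lambda0: 0.032
Gamma: 20.0
f: 0.01
A: 40.0
Q: 0.06
L0: 4.0
R: 10.0
Kmin: 0.1
Kmax: 0.6
Mmin: 0.5
Mmax: 0.9
Ymin: 0.5
Ymax: 1.5
P: 150
'N': 128
DB: 1.0
DW: 100.0
DH: 10000.0
Dchi: 1.0e-6
alpha: 0
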