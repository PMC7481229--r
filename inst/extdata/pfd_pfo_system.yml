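# Fluorinated-oil / mother-liquor T-junction system
# (10:1 perfluorodecalin : 1H,1H,2H,2H-perfluorooctanol continuous phase)
name: pfd_pfo_10_1
viscosity_mpas: 13.3
tension_mn_m: 12
width_um: 100
depth_um: 75
dispersed_diameter_um: 50
prefactor_m_s: 3.7
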