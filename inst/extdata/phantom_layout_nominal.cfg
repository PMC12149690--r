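# Nominal 13-vial isotropic PVP diffusion phantom layout.
# Reference ADC values (um2/ms at 0 C) are serial-number specific; geometry
# (ring radii 33/66 mm, vial radius 15 mm) is nominal, with vial IDs running
# clockwise from 12 o'clock in each ring. s0_scale is the nominal relative
# b=0 signal of each fill (T2-weighting at long echo times), informational
# for simulation only.
phantom.serial = nominal
phantom.radius_mm = 97
phantom.slab_thickness_mm = 40
phantom.temperature_c = 0
vial.01.ring = center
vial.01.pvp_percent = 0
vial.01.reference_adc = 1.109
vial.01.x_mm = 0
vial.01.y_mm = 0
vial.01.radius_mm = 15
vial.01.s0_scale = 1.00
vial.02.ring = inner
vial.02.pvp_percent = 0
vial.02.reference_adc = 1.109
vial.02.x_mm = 0
vial.02.y_mm = 33
vial.02.radius_mm = 15
vial.02.s0_scale = 1.00
vial.03.ring = outer
vial.03.pvp_percent = 0
vial.03.reference_adc = 1.109
vial.03.x_mm = 0
vial.03.y_mm = 66
vial.03.radius_mm = 15
vial.03.s0_scale = 1.00
vial.04.ring = inner
vial.04.pvp_percent = 10
vial.04.reference_adc = 0.817
vial.04.x_mm = 28.58
vial.04.y_mm = 16.5
vial.04.radius_mm = 15
vial.04.s0_scale = 0.55
vial.05.ring = outer
vial.05.pvp_percent = 10
vial.05.reference_adc = 0.817
vial.05.x_mm = 57.16
vial.05.y_mm = 33
vial.05.radius_mm = 15
vial.05.s0_scale = 0.55
vial.06.ring = inner
vial.06.pvp_percent = 20
vial.06.reference_adc = 0.579
vial.06.x_mm = 28.58
vial.06.y_mm = -16.5
vial.06.radius_mm = 15
vial.06.s0_scale = 0.35
vial.07.ring = outer
vial.07.pvp_percent = 20
vial.07.reference_adc = 0.579
vial.07.x_mm = 57.16
vial.07.y_mm = -33
vial.07.radius_mm = 15
vial.07.s0_scale = 0.35
vial.08.ring = inner
vial.08.pvp_percent = 30
vial.08.reference_adc = 0.380
vial.08.x_mm = 0
vial.08.y_mm = -33
vial.08.radius_mm = 15
vial.08.s0_scale = 0.24
vial.09.ring = outer
vial.09.pvp_percent = 30
vial.09.reference_adc = 0.380
vial.09.x_mm = 0
vial.09.y_mm = -66
vial.09.radius_mm = 15
vial.09.s0_scale = 0.24
vial.10.ring = inner
vial.10.pvp_percent = 40
vial.10.reference_adc = 0.220
vial.10.x_mm = -28.58
vial.10.y_mm = -16.5
vial.10.radius_mm = 15
vial.10.s0_scale = 0.17
vial.11.ring = outer
vial.11.pvp_percent = 40
vial.11.reference_adc = 0.220
vial.11.x_mm = -57.16
vial.11.y_mm = -33
vial.11.radius_mm = 15
vial.11.s0_scale = 0.17
vial.12.ring = inner
vial.12.pvp_percent = 50
vial.12.reference_adc = 0.110
vial.12.x_mm = -28.58
vial.12.y_mm = 16.5
vial.12.radius_mm = 15
vial.12.s0_scale = 0.12
vial.13.ring = outer
vial.13.pvp_percent = 50
vial.13.reference_adc = 0.110
vial.13.x_mm = -57.16
vial.13.y_mm = 33
vial.13.radius_mm = 15
vial.13.s0_scale = 0.12
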