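# Reference REEC parameter set (oxygen and glucose in culture media at
# 37 C over a confluent 4T1 monolayer).  All lengths in um, times in s,
# concentrations in uM unless the key says otherwise.

[geometry]
r_inner_um = 350          # aperture radius
r_outer_um = 6000         # chamber inner-wall radius (12 mm ID O-ring)
height_um = 100           # nominal spacer height used by the simulation
hole_diameter_um = 740.1  # as-built mean aperture diameter

[oxygen]
D_um2_s = 3370
A_max_molecules_cell_s = 2.98e7   # mito-stress-test OCR, 4T1
C_bulk_uM = 171                   # aperture boundary value, see [column]

[glucose]
D_um2_s = 616
A_max_molecules_cell_s = 6.47e7
C_bulk_uM = 25000                 # 25 mM, high-glucose DMEM

[consumers]
areal_density_cells_cm2 = 200000  # confluent monolayer

[column]
height_um = 250       # 100 um chamber + 150 um cover glass
C_top_uM = 178        # air-saturated media above the chamber

[simulation]
t_end_s = 172800      # 48 h
inspection_interval_s = 60
rms_tol = 0.001       # 0.1% relative RMS change between profiles
spacing_um = 10
output_interval_s = 3600

[profiling]
bin_width_um = 50
smooth_window = 5
front_fraction = 0.9

[synth]
noise_sigma = 0.2
I_max = 1000
background = 0
density_cells_cm2 = 200000
image_scale_um_px = 10
psf_sigma_um = 5
tile_amplitude = 0
tile_period_um = 500
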