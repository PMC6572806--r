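# North-Pond-like synthetic scenario: an 80 m oligotrophic ridge-flank
# sediment column oxygenated from the bottom seawater above and the basaltic
# aquifer below, deposited over ~8 Myr.  All model defaults are stated
# explicitly.
column:
  depth_max: 80          # m
  n_nodes: 200
  porosity: 0.7
  temperature: 1.5       # degC, bottom seawater
  burial_velocity: 1.0e-5  # m/yr (80 m / 8 Myr)
  D0:                    # free-solution diffusivities at 1.5 degC, m2/yr
    O2: 0.038548
    NO3: 0.031815
    NH4: 0.031933
    Mn2: 0.010317
  bc:
    O2:   {top: 250.0, bottom: 160.0}   # uM Dirichlet
    NO3:  {top: 21.0,  bottom: 21.1}    # uM; bottom = crustal fluid
    NH4:  {top: 0.0,   bottom: 0.0}
    Mn2:  {top: 0.0,   bottom: 0.0}
    OM:   {flux_top: 1.5e-3}            # mol C m-2 yr-1 deposition
    MnO2: {flux_top: 2.0e-7}            # mol m-2 yr-1
  solute_advection: false
kinetics:
  k_OM: 3.3e-8      # 1/yr, single-pool OM decay
  K_O2: 1.0         # uM
  K_NO3: 700.0      # uM, effective (see methods vignette)
  h1: 10.0          # uM, denitrification O2 inhibition (true value)
  K_MnO2: 5.0       # mol/m3
  h2: 1.0           # uM
  h3: 5.0           # uM
  k_nit: 6.0e-6     # 1/(uM yr)
  k_mnox: 2.0e-6    # 1/(uM yr)
  rN: 0.1509434     # 16/106, Redfield
profile_depths: {from: 0.5, to: 79.5, by: 1.0}   # m
sample_depths:  {from: 0.5, to: 79.5, by: 3.0}   # m, core horizons
noise:
  profile: 0.02             # relative sd, multiplicative lognormal
  abundance_log10: 0.15     # sd of log10 copies
  abundance_rel_sd: 0.2     # reported qPCR relative sd
abundance:
  surface: 1.0e+8           # total 16S copies per g wet sediment at 0 m
  decay_length:             # m per decade of decline, per marker
    default: 30             # 16S pool: 2-3 decades over the column
    amoA_AOA: 16            # functional genes decline 4-5 decades
    amoA_AOB: 16
    nxrB: 16
    narG: 22
    nirK: 18
    nirS: 22
  peak_fold: 100            # fold-increase at transition-zone centres
  peak_width: 2             # m
  marker_fractions:
    16S_bac: 0.5
    16S_arc: 0.5
    amoA_AOA: 0.4
    amoA_AOB: 0.004
    nxrB: 0.004
    narG: 0.01
    nirK: 0.01
    nirS: 0.005
  detection_limit: 100      # copies per g
community:
  n_otus: 600
  shape: 0.9995             # log-series parameter
  decay_scale: 2.5          # m, median per-OTU e-folding depth
  decay_sdlog: 0.8
  resurrection_p: 0.75
  reads: 8000
o2_detection_limit: 3       # uM
seed: 1
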