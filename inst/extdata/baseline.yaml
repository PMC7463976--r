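# Baseline configuration: 200 bp capped cylindrical particle translocating a
# 5 nm solid-state nanopore in 10 mol/m3 KCl at a nominal field of 2 MV/m.
# All keys are optional; omitted ones default to these values. SI units
# unless a _nm / _bp / _MV_per_m suffix says otherwise.
eps_f: 7.08e-10      # fluid permittivity (F/m)
rho_f: 1.0e+3        # fluid density (kg/m3)
mu: 1.0e-3           # dynamic viscosity (Pa s)
T_K: 300             # temperature (K)
C0: 10               # bulk KCl concentration (mol/m3)
D1: 1.95e-9          # K+ diffusivity (m2/s)
D2: 2.03e-9          # Cl- diffusivity (m2/s)
W_nm: 100            # reservoir width (axisymmetric radius W/2)
H_nm: 200            # height of each reservoir
h_nm: 5              # membrane thickness
b_nm: 5              # pore diameter
a_nm: 1              # particle cap radius
L_p_bp: 200          # particle end-to-end length (1 bp = 0.34 nm)
y_p_bp: -300         # initial particle position (below the pore)
E_nom_MV_per_m: 2    # nominal field; phi_0 = E_nom * (2H + h)
sigma_p: -0.01       # particle surface charge density (C/m2)
eps_p: 7.08e-10      # particle permittivity (baseline: same as the fluid)
bl_frac: 0.3333333   # boundary-layer element size / Debye length
h_bulk: 1.6e-9       # bulk element size (m)
picard_tol: 0.005    # coupling loop relative tolerance
picard_max: 100
relax: 0.5           # under-relaxation factor
ff_tol: 1.0e-3       # force-free velocity relative tolerance
mode: axisymmetric
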