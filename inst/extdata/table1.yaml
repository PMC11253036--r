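# Default physiological parameter set for an idealized (spherical) mouse
# popliteal lymph node.  Unit system: mm - mg - s - mPa (1 mPa = 1 mg mm^-1 s^-2).
# Derived fields (mu_e, V_m_tot, U) are resolved in code, not stored here.
R: 0.49                    # lymphoid-compartment radius [mm]
mu: 1.0                    # lymph dynamic viscosity [mg mm^-1 s^-1]
phi: 0.75                  # porosity of the conduit network [-]
rho0: 1.0                  # lymph density [mg mm^-3]
sigma: 0.88                # Staverman reflection coefficient [-]
pi_v_minus_pi_m: 1.02e6    # osmotic pressure difference pi_v - pi_m [mPa]
Lp: 5.475e-10              # vessel-wall hydraulic conductivity [mm s^-1 mPa^-1]
pbar_v: 6.66e5             # mean blood-vessel boundary pressure [mPa]
S_tot: 13.4                # total blood-vessel surface [mm^2]
V_v_tot: 0.0322            # total blood-vessel volume [mm^3]
r_c: 1.7e-3                # microscale vessel-cylinder radius [mm]
d: 2.0e-2                  # microscale cylinder spacing (cell edge) [mm]
L: 1.0                     # macroscale characteristic length [mm]
K_m_interstitial: 3.84e-9  # interstitial permeability [mm^2]
eta: 0.1                   # inertia number rho0*U*d^2/(mu*L) [-]
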