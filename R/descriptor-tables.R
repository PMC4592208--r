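# Frozen contribution tables for the additive descriptors.
# These are the package's versioned schemes; they are deliberately plain
# data so an independent oracle can re-sum them atom by atom.

DESCRIPTOR_TABLE_VERSION <- "1.0"

# Standard atomic weights (g/mol), including hydrogen for MW assembly.
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Se = 78.971, As = 74.922
)

# Element-additive atomic polarizabilities (A^3); hydrogen included.
ATOMIC_POLARIZABILITY <- c(
  H = 0.667, B = 3.03, C = 1.76, N = 1.10, O = 0.802, F = 0.557,
  Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35,
  Se = 3.77, As = 4.31
)

# Fragment-additive topological polar surface area contributions (A^2)
# for N/O-centred polar environments (Ertl-type scheme). Keys encode
# the atom environment resolved by .tpsaKey(); values are the published
# fragment contributions. Atoms not listed (C, S, P, halogens) score 0.
TPSA_CONTRIB <- c(
  # nitrogen
  "N_3s"        = 3.24,   # tertiary amine N(-*)3
  "N_1s1d"      = 12.36,  # imine-type =N-
  "N_1t"        = 23.79,  # nitrile N
  "N_2s1d"      = 11.68,  # =N< with two single bonds
  "N_H1_2s"     = 12.03,  # secondary amine N-H
  "N_H2_1s"     = 26.02,  # primary amine N-H2
  "N_H1_1s1d"   = 23.85,  # =N-H
  "N_ar2"       = 12.89,  # aromatic n with two ring bonds
  "N_ar3"       = 4.41,   # aromatic n fused (three aromatic bonds)
  "N_ar2_1s"    = 4.93,   # substituted aromatic n
  "N_ar2_H1"    = 15.79,  # aromatic n-H (pyrrole-type)
  "N+_4s"       = 0.00,
  "N+_H1_3s"    = 4.44,
  "N+_H2_2s"    = 16.61,
  "N+_H3_1s"    = 27.64,
  "N+_2s1d"     = 3.01,   # charged =N< (nitro-type written charge-separated)
  # oxygen
  "O_2s"        = 9.23,   # ether / ester O
  "O_1d"        = 17.07,  # carbonyl / sulfonyl =O
  "O_H1_1s"     = 20.23,  # hydroxyl O-H
  "O_ar2"       = 13.14,  # aromatic o (furan-type)
  "O-_1s"       = 23.06   # oxyanion
)

# generic fallbacks for polar environments the key scheme does not cover
TPSA_GENERIC <- c(N = 3.24, O = 9.23)

# Atom-typed additive logP contributions (Crippen-type scheme, frozen).
# Heavy-atom types are resolved by .clogpKey(); hydrogen contributions
# are per attached H, split by the heavy atom that carries them.
CLOGP_CONTRIB <- c(
  "C_aliph"   =  0.1441,  # sp3/sp2 aliphatic carbon
  "C_ar"      =  0.1581,  # aromatic carbon
  "C_carbonyl" = -0.1002, # carbon double-bonded to O
  "N_aliph"   = -1.0190,
  "N_ar"      = -0.3239,
  "N_amide"   = -0.6027,
  "O_hydroxyl" = -0.3567,
  "O_ether"   = -0.1526,
  "O_carbonyl" = -0.1444,
  "O_ar"      =  0.1552,
  "S_any"     =  0.6482,
  "P_any"     =  0.8612,
  "F_any"     =  0.4202,
  "Cl_any"    =  0.6895,
  "Br_any"    =  0.8456,
  "I_any"     =  0.8857,
  "B_any"     = -0.3187,
  "Si_any"    =  0.8000,
  "Se_any"    =  0.6482,
  "As_any"    =  0.8612,
  # hydrogen contributions, by carrier
  "H_on_C"    =  0.1230,
  "H_on_hetero" = -0.2677
)

# element-level fallbacks when an atom type is outside the table
CLOGP_ELEMENT_FALLBACK <- c(
  C = 0.1441, N = -1.0190, O = -0.2893, S = 0.6482, P = 0.8612,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857, B = -0.3187,
  Si = 0.8, Se = 0.6482, As = 0.8612
)
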