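{
  "_comment": "Synthetic reconstruction of the named descriptor feature sets from the main-text descriptor families (the original membership list lives in a supplementary archive that is not shipped). Counts and the inclusion lattice are enforced by the package: X_full 34, X_noTS 25, X_trad 20, X_surf 13, X_small 12.",
  "columns_ts": ["dG_dft", "q_C_TS", "q_N_TS", "q_L_TS", "V_N_C_TS",
                 "V_N_N_TS", "V_N_L_TS", "BO_CN_TS", "BO_CL_TS"],
  "columns_surface": ["Vs_C", "Vs_N", "Is_min_N", "Es_min_C", "P_int"],
  "columns_electronic": ["omega", "N_global", "omega_loc_C", "N_loc_N",
                         "q_C", "q_N", "q_L", "V_N_C", "V_N_N", "V_N_L",
                         "BO_CN", "BO_CL"],
  "columns_steric": ["SASA_C", "SASA_N", "SASA_L"],
  "columns_solvent": ["PC1", "PC2", "PC3", "PC4", "PC5"],
  "sets": {
    "X_full": ["dG_dft", "q_C_TS", "q_N_TS", "q_L_TS", "V_N_C_TS",
               "V_N_N_TS", "V_N_L_TS", "BO_CN_TS", "BO_CL_TS",
               "Vs_C", "Vs_N", "Is_min_N", "Es_min_C", "P_int",
               "omega", "N_global", "omega_loc_C", "N_loc_N",
               "q_C", "q_N", "q_L", "V_N_C", "V_N_N", "V_N_L",
               "BO_CN", "BO_CL", "SASA_C", "SASA_N", "SASA_L",
               "PC1", "PC2", "PC3", "PC4", "PC5"],
    "X_noTS": ["Vs_C", "Vs_N", "Is_min_N", "Es_min_C", "P_int",
               "omega", "N_global", "omega_loc_C", "N_loc_N",
               "q_C", "q_N", "q_L", "V_N_C", "V_N_N", "V_N_L",
               "BO_CN", "BO_CL", "SASA_C", "SASA_N", "SASA_L",
               "PC1", "PC2", "PC3", "PC4", "PC5"],
    "X_trad": ["omega", "N_global", "omega_loc_C", "N_loc_N",
               "q_C", "q_N", "q_L", "V_N_C", "V_N_N", "V_N_L",
               "BO_CN", "BO_CL", "SASA_C", "SASA_N", "SASA_L",
               "PC1", "PC2", "PC3", "PC4", "PC5"],
    "X_surf": ["Vs_C", "Vs_N", "Is_min_N", "Es_min_C", "P_int",
               "SASA_C", "SASA_N", "SASA_L",
               "PC1", "PC2", "PC3", "PC4", "PC5"],
    "X_small": ["dG_dft", "Es_min_C", "Is_min_N", "Vs_C", "Vs_N",
                "omega", "N_global", "q_C", "BO_CL", "SASA_C",
                "PC1", "PC2"]
  }
}
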