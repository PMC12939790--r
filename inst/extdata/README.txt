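mock_met.csv -- SYNTHETIC mock augmented multi-environment trial.

Generated with the package's own generator (not field data):

  simulate_met(g_lines = 30, n_env = 4, n_checks = 4, reps_per_check = 4,
               mu = 7, sd_gen = 1.2, sd_env = 1.5,
               interaction_rank = 3, lambda_shares = c(0.5, 0.33, 0.17),
               sd_int = 0.6, sd_noise = 0.8, planted_stable = 2,
               stable_yield_bonus = 1, seed = 4217)

Layout: 30 unreplicated lines (G1..G30; G1 and G2 planted stable with a
+1 t/ha yield bonus) plus 4 check cultivars (CHK1..CHK4) replicated in
quadruplicate in blocks B1..B4, in each of 4 environments (E1..E4).
Columns: environment, genotype, block, role (check|line), yield (t/ha).
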