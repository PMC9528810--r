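# Shared fixtures, generated once per test run. Sizes are kept moderate so
# the whole suite stays well inside a single-CPU budget.

.fixture_env <- new.env(parent = emptyenv())

# one medium synthetic dataset reused by several files
fixture_dataset <- function() {
  if (is.null(.fixture_env$d))
    .fixture_env$d <- synth_generate(synth_config(n_samples = 350, seed = 42))
  .fixture_env$d
}

fixture_xy <- function(set = "X_full") {
  key <- paste0("xy_", set)
  if (is.null(.fixture_env[[key]])) {
    d <- fixture_dataset()
    .fixture_env[[key]] <-
      assemble_features(d$reactions, d$descriptors, feature_set_spec(set))
  }
  .fixture_env[[key]]
}

# tiny hand-built reaction table (3 rows, Eyring-consistent)
tiny_reactions <- function() {
  tK <- c(298.15, 320, 350)
  dG <- c(20, 24, 18)
  data.frame(rxn_id = c("r1", "r2", "r3"),
             reaction_smiles = c("Fc1ccccc1>>Oc1ccccc1",
                                 "Fc1ccccc1>>Oc1ccccc1",
                                 "Clc1ccccc1>>Oc1ccccc1"),
             nucleophile_class = c("N-neutral", "N-neutral", "O-anionic"),
             leaving_class = c("F", "F", "Cl"),
             electrophile_id = c("E1", "E1", "E2"),
             nucleophile_id = c("Nu1", "Nu1", "Nu2"),
             solvent = c("water", "methanol", "water"),
             temperature_K = tK,
             k_obs = inverse_eyring(dG, tK),
             dG_exp_kcal = dG,
             stringsAsFactors = FALSE)
}
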