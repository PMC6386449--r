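# shared fixtures: reference parameter sets and small builders

ref_params <- function() ta_params_table1("derived")

ref_norm <- function(delta_a = NULL, epsilon = NULL) {
  np <- normalize_params(ref_params())
  if (!is.null(delta_a) || !is.null(epsilon)) {
    np <- set_stress(np, delta_a = delta_a, epsilon = epsilon)
  }
  np
}

# single-species birth-death system: 0 -> X at `birth`, X -> 0 at
# `death` per molecule
birth_death <- function(birth, death) {
  reaction_system("X", list(
    list(change = 1L, rate = birth, order = 0),
    list(change = -1L, rate = death, order = 1, s1 = "X")))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)),
            tol)
}
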