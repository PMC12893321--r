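# tiny constructors shared across test files

# trio_set from plain vectors (one trio) or matrices
make_trios <- function(father, mother, offspring) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(as.integer(x), nrow = 1)
  trio_set(as_m(father), as_m(mother), as_m(offspring))
}

# small scaled layout + scenarios used by the simulator tests
test_layout <- function(q = 1 / 20) genome_layout(scale_factor = q)

neutral_dfe <- function() dfe_config(neutral_prop = 0.999999,
                                     gamma_mean = -1e-9)

# binomial 95% CI half-width
binom_ci <- function(p, n, z = 1.96) z * sqrt(p * (1 - p) / n)
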