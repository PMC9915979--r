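# Shared builders for small test objects.

tiny_comp <- function(Q = 1, V = 10, P = 2, name = "liver") {
  compartment_params(name, Q = Q, V = V, P = P)
}

# Random but valid parameter sets for property-style tests; draws are
# log-uniform so magnitudes vary over decades.
random_pbpk_parameters <- function() {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  pbpk_parameters(
    compartments = list(
      compartment_params("richly_perfused", lu(0.1, 5), lu(0.5, 10), lu(0.5, 5)),
      compartment_params("fat", lu(0.05, 1), lu(1, 10), lu(10, 60)),
      compartment_params("poorly_perfused", lu(0.1, 5), lu(5, 40), lu(0.3, 3)),
      compartment_params("liver", lu(0.2, 3), lu(0.3, 3), lu(0.5, 5))
    ),
    metabolism = metabolism_params(Vmax = lu(0.05, 2), Km = lu(0.05, 2),
                                   f_ttma = stats::runif(1, 0.005, 0.1))
  )
}

random_physiology <- function() {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  physiology(age = stats::runif(1, 6, 12), body_weight = lu(18, 50),
             P_blood_air = lu(5, 12), Q_alv = lu(1, 4), Q_card = lu(2, 5),
             urine_void_volume = lu(0.08, 0.4),
             urinary_creatinine = lu(0.4, 2))
}
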