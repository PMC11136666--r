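# fixtures built in code

sem <- function(x) stats::sd(x) / sqrt(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# random MID on the simplex
random_mid <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

# two-carbon toy fragment: 1 labelable backbone C + 1 derivative C
toy_fragment <- function(n_channels = 2) {
  fragment("toy", c(C = 2, H = 0, O = 0), base_mz = 100,
           n_channels = n_channels, n_label_positions = 1)
}

# abundances with every heavy isotope switched off
null_abundances <- function() {
  isotope_abundances(C = 0, H = 0, N = 0, O = c(0, 0),
                     Si = c(0, 0), S = c(0, 0))
}

zero_noise_truth <- function(n_animals = 3, seed = 7, ...) {
  simulation_truth(n_animals = n_animals, noise_cv = 0,
                   between_animal_cv = 0, seed = seed, ...)
}
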