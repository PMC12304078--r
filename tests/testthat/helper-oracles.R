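# Independent closed-form oracles for the receptor-noise-limited contrasts.
# These transcribe the dichromat and trichromat formulas directly and share
# no code with the package's quadratic-form implementation.

oracle_dichromat_jnd <- function(df, e) {
  abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)
}

oracle_trichromat_jnd <- function(df, e) {
  num <- e[1]^2 * (df[3] - df[2])^2 +
         e[2]^2 * (df[3] - df[1])^2 +
         e[3]^2 * (df[1] - df[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

oracle_achromatic_jnd <- function(la, lb, omega) abs(log(la / lb)) / omega

random_catch_pair <- function(observer) {
  k <- length(observer$peaks)
  list(a = cone_catch(exp(stats::rnorm(k, 0, 1)), observer),
       b = cone_catch(exp(stats::rnorm(k, 0, 1)), observer))
}

# quick builders used across test files
porcus <- function() visual_system("scorpaena_porcus")
delaisi <- function() visual_system("tripterygion_delaisi")

flat_spectrum <- function(value, grid = wl_grid(), kind = "reflectance") {
  make_spectrum(rep(value, length(wavelengths(grid))), grid, kind)
}
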