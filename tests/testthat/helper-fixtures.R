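# Fixtures built in code: small event tables and exact Arrhenius data.

# events tibble from a named list of per-embryo score-time maps
make_events <- function(..., organism = "fly", temperature_C = 25) {
  embryos <- list(...)
  purrr::imap_dfr(embryos, function(times, id) {
    tibble::tibble(
      embryo_id = id,
      organism = organism,
      temperature_C = temperature_C,
      score_code = names(times),
      time_min = unname(unlist(times))
    )
  })
}

# exact Arrhenius observations: ln k = lnA - Ea/(R T)
exact_arrhenius_points <- function(Ea_kJ, lnA, temperatures_C) {
  T_K <- temperatures_C + 273.15
  tibble::tibble(
    temperature_C = temperatures_C,
    rate_per_min = exp(lnA - Ea_kJ * 1000 / 8.314 / T_K)
  )
}

# replicate exact observations with multiplicative lognormal rate noise
noisy_arrhenius_points <- function(Ea_kJ, lnA, temperatures_C,
                                   replicates = 5, sdlog = 0.05) {
  base <- exact_arrhenius_points(Ea_kJ, lnA, rep(temperatures_C, each = replicates))
  base$rate_per_min <- base$rate_per_min *
    exp(stats::rnorm(nrow(base), 0, sdlog))
  base
}
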