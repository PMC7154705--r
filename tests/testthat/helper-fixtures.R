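# Shared fixtures, built once per test run.

# the standard synthetic region (noiseless, known ground truth)
syn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic_region(synthetic_config(seed = 42))
    }
    cache
  }
})

# a small constant-forcing dataset: constant area and harvest, zero anomaly,
# no land conversion; handy for equilibrium and ledger checks
constant_dataset <- function(years = 1850:2015, area_dec = 2e5,
                             area_con = 1e5, h_dec = 0.3, h_con = 0.35) {
  yrs <- range(years)
  regional_dataset(
    region_id = "const", latitude = 46, years = years,
    area = dplyr::bind_rows(
      tibble::tibble(year = yrs, group = "deciduous", value = area_dec),
      tibble::tibble(year = yrs, group = "coniferous", value = area_con)),
    harvest = dplyr::bind_rows(
      tibble::tibble(year = yrs, group = "deciduous",
                     value = h_dec * area_dec),
      tibble::tibble(year = yrs, group = "coniferous",
                     value = h_con * area_con))
  )
}

default_params <- function() {
  tibble::tibble(group = c("deciduous", "coniferous"),
                 r = c(0.12, 0.16), K = c(180, 140))
}
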