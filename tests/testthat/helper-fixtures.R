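# Shared fixtures: tiny guest panels and simulation settings used across
# test files. Everything is built in code.

toy_guests <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    name = c("alpha", "beta", "gamma", "delta"),
    volume = c(40, 80, 120, 160),
    sigma_prime = effective_diameter(c(40, 80, 120, 160)),
    alpha = c(3, 6, 9, 12),
    solv_water = c(1, 0.5, 0, -0.5),
    solv_benzene = c(-1, -2, -3, -4),
    solv_pfh = c(-0.5, -1, -1.5, -2),
    cav_benzene = c(5, 7, 9, 11),
    cav_pfh = c(1.5, 2, 2.5, 3),
    stringsAsFactors = FALSE
  )
}

# benzene-mimic panel of the nine rigid hydrocarbons used in the packaged
# competition experiments
p3_panel_ids <- c("12", "13", "14", "15", "16", "17", "18", "19", "21")
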