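# Shared fixtures, built in code.

# A small city reused by several tests (cheap: ~0.1 s).
tiny_city <- function(seed = 1L, n_areas = 16L, n_units = 4L, ...) {
  simulate_city(n_areas = n_areas, n_units = n_units, mean_pop = 6000,
                seed = seed, ...)
}

# Single-sex deaths/exposure matrices for a handmade model.
toy_model <- function(n_areas = 2L, ages = 0:5, knots = c(0, 5),
                      m_true = 0.05, exposure = 1e4,
                      adjacency = NULL, tau_spatial = 5, tau_shape = 2,
                      seed = 1L) {
  set.seed(seed)
  areas <- sprintf("T%02d", seq_len(n_areas))
  N <- matrix(exposure, n_areas, length(ages), dimnames = list(areas, ages))
  D <- matrix(rpois(n_areas * length(ages), exposure * m_true),
              n_areas, length(ages), dimnames = list(areas, ages))
  std <- standard_schedule(ages, rep(log(m_true), length(ages)))
  if (is.null(adjacency)) {
    adjacency <- if (n_areas > 1) {
      data.frame(area_i = areas[-n_areas], area_j = areas[-1])
    } else {
      data.frame(area_i = character(0), area_j = character(0))
    }
  }
  topals_model(D, N, std, adjacency, knots = knots,
               tau_spatial = tau_spatial, tau_shape = tau_shape)
}

# Continuous-time life expectancy under a piecewise-constant hazard:
# closed-form integration of the survival curve, age by age, plus the
# open-interval tail. Independent of the life-table engine.
le_piecewise_exact <- function(mx, at = 0) {
  n <- length(mx)
  S <- 1
  e <- 0
  for (x in seq_len(n - 1)) {
    if (x - 1 >= at) {
      e <- e + S * (1 - exp(-mx[x])) / mx[x]
      S <- S * exp(-mx[x])
    }
  }
  e + S / mx[n]
}
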