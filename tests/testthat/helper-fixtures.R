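# Shared fixtures, all built in code.

# law table for a reduced 2-generation world, deterministic when sigma = 0
tiny_laws <- function(sigma_x = 0, sigma_a = 0, sigma_b = 0,
                      generations = 6:8) {
  laws <- default_group_laws(generations)
  laws$sigma[laws$feature == "x"] <- sigma_x
  laws$sigma[laws$feature == "a"] <- sigma_a
  laws$sigma[laws$feature == "b"] <- sigma_b
  laws$sigma[laws$feature %in% c("m", "vbar", "sbar")] <- 0
  laws
}

# minimal hand-built lineage: one mother (id 1) observed at t = 0..8,
# dividing at t = 10 into daughters 2 and 3 observed t = 10..18
toy_tree <- function(vol_mother = 100, vol_daughters = c(50, 50)) {
  steps <- seq(0, 8, by = 2)
  rec <- rbind(
    data.frame(cell_id = 1L, mother_id = NA_integer_, t = steps,
               x = 0, y = 0, z = 0, type = "Mes",
               volume = vol_mother, surface = 4.836 * vol_mother^(2 / 3)),
    data.frame(cell_id = 2L, mother_id = 1L, t = steps + 10,
               x = 1, y = 0, z = 0, type = "Mes",
               volume = vol_daughters[1], surface = 4.836 * vol_daughters[1]^(2 / 3)),
    data.frame(cell_id = 3L, mother_id = 1L, t = steps + 10,
               x = -1, y = 0, z = 0, type = "Mes",
               volume = vol_daughters[2], surface = 4.836 * vol_daughters[2]^(2 / 3))
  )
  lineage_tree(rec, window = c(0, 18))
}

# numerical-quadrature oracle for the KL divergence between two laws,
# independent of the package's closed forms
kl_quadrature <- function(p, q) {
  if (p$family == "normal") {
    f <- function(x) {
      dnorm(x, p$mu, p$sigma) *
        (dnorm(x, p$mu, p$sigma, log = TRUE) - dnorm(x, q$mu, q$sigma, log = TRUE))
    }
    integrate(f, p$mu - 12 * p$sigma, p$mu + 12 * p$sigma,
              rel.tol = 1e-10)$value
  } else {
    f <- function(x) {
      d <- dlnorm(x, p$mu, p$sigma)
      out <- d * (dlnorm(x, p$mu, p$sigma, log = TRUE) -
                    dlnorm(x, q$mu, q$sigma, log = TRUE))
      out[!is.finite(out)] <- 0
      out
    }
    integrate(f, qlnorm(1e-12, p$mu, p$sigma), qlnorm(1 - 1e-12, p$mu, p$sigma),
              rel.tol = 1e-9, subdivisions = 500L)$value
  }
}

# points on a sphere with per-point radius r_cell, latitude-banded types
shell_state <- function(n = 64, R0 = 30, r_cell = 10,
                        types = NULL) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(1 - z^2, 0))
  pos <- R0 * cbind(rho * cos(phi), rho * sin(phi), z)
  if (is.null(types)) {
    types <- rep(CELL_TYPES, times = round(n * c(0.5, 0.25, 0.125, 0.125)))
    types <- types[seq_len(n)]
  }
  mech_state(pos, rep(r_cell, n), types)
}
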