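#' Parameters of the biomechanical model
#'
#' Coefficients of the overdamped particle model. `omega_rep` scales the
#' repulsive branch of the pair force (cell stiffness), `omega_adh_o` /
#' `omega_adh_e` the homotypic / heterotypic adhesive branch, and `k_rig`
#' the planarity-conservation force that keeps the epithelium monolayered
#' (the implicit blastocoel turgor pressure). `c_eq` and `c_max` are the
#' dimensionless multipliers of the mean cell radius defining the
#' equilibrium distance `r_eq = c_eq (R_i + R_j)/2` and the maximum contact
#' distance `r_max = c_max (R_i + R_j)/2`. `lambda` is the damping
#' coefficient of the overdamped equation of motion; `dt_max` caps the
#' integrator step and `disp_cap` caps the per-step displacement as a
#' fraction of the smallest `r_eq`.
#'
#' @param omega_rep,omega_adh_o,omega_adh_e,k_rig Force coefficients
#'   (`>= 0`).
#' @param c_eq,c_max Radii multipliers, `0 < c_eq < c_max`.
#' @param lambda Damping (`> 0`).
#' @param dt_max Maximum integrator step (min).
#' @param disp_cap Per-step displacement cap (fraction of min `r_eq`).
#' @param relax_steps Maximum relaxation steps between division events.
#' @param relax_tol Convergence threshold on per-step displacement, as a
#'   fraction of the smallest `r_eq`.
#' @return A list of class `mech_params`.
#' @export
mech_params <- function(omega_rep = 1000, omega_adh_o = 100, omega_adh_e = 30,
                        k_rig = 600, c_eq = 0.9, c_max = 1.3, lambda = 1,
                        dt_max = 0.2, disp_cap = 0.1,
                        relax_steps = 200L, relax_tol = 1e-3) {
  stopifnot(c_eq > 0, c_max > c_eq, lambda > 0, dt_max > 0,
            omega_rep >= 0, omega_adh_o >= 0, omega_adh_e >= 0, k_rig >= 0)
  structure(list(
    omega_rep = omega_rep, omega_adh_o = omega_adh_o,
    omega_adh_e = omega_adh_e, k_rig = k_rig, c_eq = c_eq, c_max = c_max,
    lambda = lambda, dt_max = dt_max, disp_cap = disp_cap,
    relax_steps = as.integer(relax_steps), relax_tol = relax_tol
  ), class = "mech_params")
}

#' Interaction radius of a cell from its volume
#'
#' Radius of the sphere of equal volume, `(3 v / 4 pi)^(1/3)`.
#'
#' @param volume Cell volume(s), um^3.
#' @return Radius in um.
#' @export
radius_from_volume <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' Mechanical state of the embryo
#'
#' @param pos n x 3 matrix of positions (um).
#' @param radius Interaction radii (um).
#' @param type Cell type labels.
#' @param cell_id Cell identifiers linking back to a lineage.
#' @param t Simulation time (min).
#' @return A list of class `mech_state`.
#' @export
mech_state <- function(pos, radius, type, cell_id = seq_len(nrow(pos)), t = 0) {
  stopifnot(ncol(pos) == 3, nrow(pos) == length(radius),
            length(radius) == length(type))
  structure(list(pos = unname(as.matrix(pos)), radius = as.numeric(radius),
                 type = as.character(type), cell_id = as.integer(cell_id),
                 t = t),
            class = "mech_state")
}

#' @export
print.mech_state <- function(x, ...) {
  cat(sprintf("<mech_state: %d particles at t = %.1f min>\n",
              nrow(x$pos), x$t))
  invisible(x)
}

#' Outward apicobasal axes of a state
#'
#' Unit vectors from the embryo centroid through each cell centre.
#'
#' @param state A [mech_state()].
#' @return n x 3 matrix of unit vectors.
#' @export
state_axes <- function(state) {
  ctr <- colMeans(state$pos)
  v <- sweep(state$pos, 2, ctr)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm < 1e-12] <- 1
  v / nrm
}

#' Cell-contact graph of a mechanical state
#'
#' Edge `(i, j)` whenever `r_ij < c_max (R_i + R_j) / 2`; symmetric by
#' construction. Uses a spatial hash above 64 particles.
#'
#' @param state A [mech_state()].
#' @param params A [mech_params()].
#' @return A data frame with columns `i`, `j` (indices, `i < j`) and `r`.
#' @export
contact_graph <- function(state, params = mech_params()) {
  cg <- .mech_contacts_cpp(state$pos, state$radius, params$c_max)
  data.frame(i = cg$i, j = cg$j, r = cg$r)
}

#' Signed magnitude of the pair force profile
#'
#' Positive = repulsive (pushes the cells apart), negative = adhesive.
#' Repulsion `omega_rep (r_eq - r)/r_eq` below the equilibrium distance; a
#' single adhesive lobe `-omega_adh 4 (r - r_eq)(r_max - r)/(r_max -
#' r_eq)^2` between `r_eq` and `r_max`, zero at both ends and beyond.
#'
#' @param r Interparticle distance(s).
#' @param Ri,Rj Cell radii.
#' @param homotypic Same cell type?
#' @param params A [mech_params()].
#' @return Signed force magnitude(s) along the interparticle axis.
#' @export
pair_force <- function(r, Ri, Rj, homotypic = TRUE, params = mech_params()) {
  r_eq <- params$c_eq * (Ri + Rj) / 2
  r_max <- params$c_max * (Ri + Rj) / 2
  w <- if (homotypic) params$omega_adh_o else params$omega_adh_e
  out <- numeric(length(r))
  rep_zone <- r < r_eq
  adh_zone <- r >= r_eq & r < r_max
  out[rep_zone] <- params$omega_rep * (r_eq - r[rep_zone]) / r_eq
  out[adh_zone] <- -w * 4 * (r[adh_zone] - r_eq) * (r_max - r[adh_zone]) /
    (r_max - r_eq)^2
  out
}

#' Attraction-repulsion force exerted by cell j on cell i
#'
#' @param state A [mech_state()].
#' @param i,j Particle indices.
#' @param params A [mech_params()].
#' @return A force 3-vector on `i`.
#' @export
attraction_repulsion <- function(state, i, j, params = mech_params()) {
  d <- state$pos[i, ] - state$pos[j, ]
  r <- sqrt(sum(d^2))
  r_max <- params$c_max * (state$radius[i] + state$radius[j]) / 2
  if (r >= r_max) return(c(0, 0, 0))
  u <- d / max(r, 1e-12)
  mag <- pair_force(r, state$radius[i], state$radius[j],
                    homotypic = state$type[i] == state$type[j], params)
  mag * u
}

#' Planarity-conservation force on one cell
#'
#' Restoring force (coefficient `k_rig`) pulling the cell into the local
#' tangent plane of its neighbourhood: for each contact the pair separation
#' is projected on the bisector of the two cells' outward normals and pushed
#' back to zero. Vanishes when the cell and its neighbours are locally
#' coplanar with aligned normals (e.g. on a common sphere with radial axes).
#'
#' @param state A [mech_state()].
#' @param i Particle index.
#' @param params A [mech_params()].
#' @return A force 3-vector on `i`.
#' @export
planarity_force <- function(i, state, params = mech_params()) {
  f <- .mech_forces_cpp(state$pos, state$radius,
                        match(state$type, CELL_TYPES), unclass(params))
  f$F_plan[i, ]
}

#' All forces on all particles
#'
#' @param state A [mech_state()].
#' @param params A [mech_params()].
#' @return List with `F_ar`, `F_plan` (n x 3 matrices) and the contact list.
#' @export
mech_forces <- function(state, params = mech_params()) {
  .mech_forces_cpp(state$pos, state$radius,
                   match(state$type, CELL_TYPES), unclass(params))
}

#' Advance a mechanical state
#'
#' Overdamped integration `x <- x + F / lambda * dt` with the step clamped
#' so no particle moves more than `disp_cap * min(r_eq)` per step; stops
#' when converged (per-step displacement below `relax_tol * min(r_eq)`) or
#' after `steps` steps.
#'
#' @param state A [mech_state()].
#' @param params A [mech_params()].
#' @param steps Maximum number of steps (default 1: a single step).
#' @return The updated state; attributes `steps`, `converged`.
#' @export
mech_step <- function(state, params = mech_params(), steps = 1L) {
  tol <- params$relax_tol * params$c_eq * min(state$radius)
  out <- .mech_integrate_cpp(state$pos, state$radius,
                             match(state$type, CELL_TYPES), unclass(params),
                             as.integer(steps), tol)
  state$pos <- out$pos
  attr(state, "steps") <- out$steps
  attr(state, "converged") <- out$converged
  state
}

#' Relax a state to mechanical quasi-equilibrium
#'
#' @param state A [mech_state()].
#' @param params A [mech_params()].
#' @param max_steps Step budget.
#' @return The relaxed state (see [mech_step()]).
#' @export
mech_relax <- function(state, params = mech_params(),
                       max_steps = params$relax_steps) {
  mech_step(state, params, steps = max_steps)
}

#' Initial 32-cell configuration on a spherical shell
#'
#' Places the root cells on a sphere with types in latitudinal bands from
#' the animal pole down: mesomeres on the animal cap, then macromeres,
#' large micromeres, and small micromeres at the vegetal pole, matching the
#' fate geography of the sea-urchin 32-cell stage. Points follow a uniform
#' spherical spiral ordered by latitude; the shell radius defaults to the
#' value at which hexagonally packed neighbours sit at the pair-force
#' equilibrium distance `spacing * mean(R)`.
#'
#' @param roots A data frame with columns `cell_id`, `k` (type) and `vbar`
#'   (volume, um^3), e.g. the root rows of a `sim_cells` table.
#' @param R0 Shell radius (um); `NULL` = automatic.
#' @param spacing Target neighbour spacing as a multiple of the mean cell
#'   radius; defaults to the `c_eq` of [mech_params()].
#' @param t Initial time stamp.
#' @return A [mech_state()].
#' @export
init_blastula <- function(roots, R0 = NULL, spacing = 0.9, t = 0) {
  n <- nrow(roots)
  radius <- radius_from_volume(roots$vbar)
  # hexagonal footprint sqrt(3)/2 d^2 per cell on a sphere of area 4 pi R0^2
  if (is.null(R0)) {
    R0 <- spacing * mean(radius) * sqrt(n * sqrt(3) / (8 * pi))
  }
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n              # descending latitude
  phi <- i * pi * (3 - sqrt(5))         # golden-angle spiral
  rho <- sqrt(pmax(1 - z^2, 0))
  pos <- R0 * cbind(rho * cos(phi), rho * sin(phi), z)
  # animal-to-vegetal band order
  ord <- order(match(roots$k, CELL_TYPES), roots$cell_id)
  st <- mech_state(pos, radius[ord], roots$k[ord], roots$cell_id[ord], t = t)
  st
}

#' Place two daughter cells at a division
#'
#' Daughters are separated by half their equilibrium distance along a
#' direction at angle `theta` inside the tangential plane (the plane
#' orthogonal to the mother's apicobasal axis), symmetric about the mother
#' centre: the division is oriented tangentially, with `theta` drawn
#' uniformly by the caller.
#'
#' @param x Mother position (3-vector).
#' @param axis Mother apicobasal unit axis.
#' @param radii Length-2 daughter radii.
#' @param theta Division angle in the tangent plane (radians).
#' @param c_eq Equilibrium-distance multiplier.
#' @return A 2 x 3 matrix of daughter positions.
#' @export
place_daughters <- function(x, axis, radii, theta, c_eq = 0.9) {
  ax <- axis / sqrt(sum(axis^2))
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  d <- cos(theta) * e1 + sin(theta) * e2
  off <- 0.25 * c_eq * (radii[1] + radii[2]) / 2
  rbind(x + off * d, x - off * d)
}

#' Embed a simulated lineage in space
#'
#' Runs the biomechanical model over the lineage's time span: starting from
#' the banded 32-cell shell, time advances in slices of `slice_dt`; at each
#' slice boundary the divisions scheduled by the lineage are executed
#' (mother replaced by her two daughters, separated by half their
#' equilibrium distance along a direction drawn uniformly in the tangential
#' plane, hence orthogonal to the apicobasal axis), then the configuration
#' relaxes by overdamped integration. Deterministic given (lineage, params,
#' seed).
#'
#' @param cells A `sim_cells` lineage table (see [simulate_lineage()]).
#' @param params A [mech_params()].
#' @param seed RNG seed for the division angles.
#' @param slice_dt Event-batching time slice (min).
#' @param checkpoint_every Keep every k-th slice state (the final state is
#'   always kept).
#' @param t_end End of the simulated span; defaults to just past the last
#'   executed division.
#' @return A list of class `mech_trajectory`: `states` (list of
#'   [mech_state()]), `times`, `params`, `seed`.
#' @export
embed_lineage <- function(cells, params = mech_params(), seed = 1L,
                          slice_dt = 2, checkpoint_every = 10L, t_end = NULL) {
  set.seed(seed)
  has_daughters <- cells$cell_id %in% cells$mother_id
  div_time <- ifelse(has_daughters, cells$m, NA_real_)
  roots <- cells[is.na(cells$mother_id), , drop = FALSE]
  t0 <- min(cells$m, na.rm = TRUE) - slice_dt
  if (is.null(t_end)) {
    t_end <- if (any(has_daughters)) max(div_time, na.rm = TRUE) + slice_dt else t0 + slice_dt
  }

  state <- init_blastula(roots, t = t0)
  state <- mech_relax(state, params)
  lut <- cells
  lut$div <- div_time
  states <- list(state)
  times <- t0
  slice_i <- 0L

  t <- t0
  while (t < t_end - 1e-9) {
    t <- min(t + slice_dt, t_end)
    slice_i <- slice_i + 1L
    # execute divisions scheduled up to t
    due <- which(state$cell_id %in% lut$cell_id[!is.na(lut$div) & lut$div <= t])
    if (length(due)) {
      axes <- state_axes(state)
      keep <- setdiff(seq_along(state$cell_id), due)
      new_pos <- state$pos[keep, , drop = FALSE]
      new_rad <- state$radius[keep]
      new_typ <- state$type[keep]
      new_ids <- state$cell_id[keep]
      for (ix in due) {
        mother <- state$cell_id[ix]
        dau <- lut[!is.na(lut$mother_id) & lut$mother_id == mother, , drop = FALSE]
        rd <- radius_from_volume(dau$vbar)
        dp <- place_daughters(state$pos[ix, ], axes[ix, ], rd,
                              theta = runif(1, 0, 2 * pi), c_eq = params$c_eq)
        new_pos <- rbind(new_pos, dp)
        new_rad <- c(new_rad, rd)
        new_typ <- c(new_typ, dau$k)
        new_ids <- c(new_ids, dau$cell_id)
      }
      state <- mech_state(new_pos, new_rad, new_typ, new_ids, t = t)
    }
    state <- mech_relax(state, params)
    state$t <- t
    if (slice_i %% checkpoint_every == 0L) {
      states[[length(states) + 1L]] <- state
      times <- c(times, t)
    }
  }
  if (times[length(times)] < t) {
    states[[length(states) + 1L]] <- state
    times <- c(times, t)
  }
  structure(list(states = states, times = times, params = params, seed = seed),
            class = "mech_trajectory")
}
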