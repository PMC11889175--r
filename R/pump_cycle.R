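#' Parameter set for the canonical pumping cycle
#'
#' Collects the energetic and kinetic inputs of the ten-step pumping cycle:
#' donor/acceptor midpoint potentials, redox-dependent Na+ binding free
#' energies at the buried site, conformational barriers, edge-to-edge
#' distances for the electron-transfer steps, the reorganization energy,
#' and the membrane coupling. Defaults are the "default" preset of
#' [make_cycle_params()].
#'
#' @param fd_mV Ferredoxin midpoint potential (mV). Default -450; the
#'   physiological range spans about -500 to -430 mV and the choice moves
#'   the break-even SMF between 180 and 130 mV.
#' @param nad_mV NAD+/NADH midpoint potential (mV), default -320.
#' @param dG_bind_oxidized_kcal,dG_bind_reduced_kcal Na+ binding free
#'   energies at the buried site with the AE1 cluster oxidised / reduced
#'   (kcal/mol), defaults -1 and -3.
#' @param barrier_conf_reduced_kcal Activation free energy of the
#'   inward/outward transition with AE1 reduced (kcal/mol), default 4.
#' @param barrier_conf_oxidized_kcal Same with AE1 oxidised, default 10
#'   (the gate that suppresses leak cycling).
#' @param barrier_binding_kcal,barrier_hydride_kcal Intrinsic barriers for
#'   Na+ uptake and the terminal hydride transfer (kcal/mol).
#' @param dG_et_chain_kcal Free-energy drop assigned to each intra-chain
#'   electron-transfer step (kcal/mol; mildly downhill by default).
#' @param dG_conf_kcal Free energy of the inward/outward transition with
#'   AE1 reduced (kcal/mol; nearly isoenergetic, default 0).
#' @param dG_hydride_kcal Free energy of the hydride-transfer step.
#' @param distances_A Named numeric vector of edge-to-edge distances
#'   (Angstrom) for the ET steps: `fd_b8` (terminal B-chain hop),
#'   `b8_ae1` (inward, gated), `ae1_fmng` (closed conformation),
#'   `fmn_chain` (flavin-chain relay).
#' @param lambda_eV Reorganization energy for all tunneling steps (eV).
#' @param electrogenic Named fractions of the membrane dielectric crossed
#'   by the Na+ in the uptake, translocation (conformational) and release
#'   steps of each stroke; must sum to 1 per Na+.
#' @param na_per_cycle Na+ pumped per full 2-electron cycle (default 2).
#' @param smf_mV Sodium-motive force applied to the model (mV).
#' @param temperature_K Temperature (K), default 310.
#' @return A named list of class `cycle_params`.
#' @export
cycle_params <- function(fd_mV = -450, nad_mV = -320,
                         dG_bind_oxidized_kcal = -1,
                         dG_bind_reduced_kcal = -3,
                         barrier_conf_reduced_kcal = 4,
                         barrier_conf_oxidized_kcal = 10,
                         barrier_binding_kcal = 3,
                         barrier_hydride_kcal = 5,
                         dG_et_chain_kcal = -0.5,
                         dG_conf_kcal = 0,
                         dG_hydride_kcal = 0,
                         distances_A = c(fd_b8 = 12, b8_ae1 = 17,
                                         ae1_fmng = 16, fmn_chain = 12),
                         lambda_eV = 0.7,
                         electrogenic = c(uptake = 0.3, translocation = 0.4,
                                          release = 0.3),
                         na_per_cycle = 2,
                         smf_mV = 0,
                         temperature_K = .DEFAULT_T_K) {
  stopifnot(all(c("fd_b8", "b8_ae1", "ae1_fmng", "fmn_chain") %in%
                  names(distances_A)),
            all(c("uptake", "translocation", "release") %in%
                  names(electrogenic)))
  if (abs(sum(electrogenic) - na_per_cycle / 2) > 1e-9) {
    stop("electrogenic fractions must sum to the charge moved per stroke ",
         "(na_per_cycle / 2)", call. = FALSE)
  }
  structure(as.list(environment()), class = "cycle_params")
}

#' Build the canonical ten-step pumping cycle
#'
#' Constructs the master-equation model of the redox-driven Na+ pumping
#' cycle: two electron-injection strokes, each comprising ferredoxin to B8
#' electron transfer, gated B8 to AE1 transfer, Na+ uptake at the buried
#' site, the inward/outward conformational transition, and AE1 to FMN(G)
#' transfer with Na+ release to the periplasm; after the second stroke a
#' hydride transfer reduces NAD+ and closes the cycle. Reverse rates are
#' set by detailed balance, and the per-step free energies are constructed
#' so the cycle closes exactly on the overall reaction free energy plus the
#' SMF work of moving `na_per_cycle` charges.
#'
#' @param params A [cycle_params()] object (default parameters if omitted).
#' @param closure_tol Tolerance (kcal/mol) on the cycle-closure residual.
#' @return An object of class `pump_cycle_model` with elements `states`
#'   (data frame), `transitions` (data frame with forward rates at SMF = 0),
#'   `thermo`, and `params`.
#' @examples
#' m <- build_canonical_cycle()
#' steady_state(m)$na_flux
#' @export
build_canonical_cycle <- function(params = cycle_params(),
                                  closure_tol = 1e-6) {
  stopifnot(inherits(params, "cycle_params"))
  p <- params
  dG_e <- -.FARADAY_KCAL * (p$nad_mV - p$fd_mV) / 1000  # per electron, kcal

  states <- data.frame(
    label = c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x"),
    electron_count = c(0L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    electron_location = c("none", "B8", "AE1", "AE1", "AE1", "FMN-C",
                          "B8", "AE1", "AE1", "FMN-C"),
    na_bound = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                 FALSE, TRUE, TRUE, FALSE),
    conformation = c("inward", "inward", "inward", "inward", "outward",
                     "inward", "inward", "inward", "outward", "inward"),
    na_pumped = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )

  eg <- p$electrogenic
  # Stroke 1: i->ii->iii->iv->v->vi ; stroke 2: vi->vii->viii->ix->x->i.
  # The last ET step of each stroke absorbs the free-energy remainder so
  # that each stroke sums to the per-electron reaction free energy.
  rem1 <- dG_e - (2 * p$dG_et_chain_kcal + p$dG_bind_reduced_kcal +
                    p$dG_conf_kcal)
  rem2 <- dG_e - (p$dG_et_chain_kcal +
                    (p$dG_et_chain_kcal + p$dG_bind_reduced_kcal) +
                    p$dG_conf_kcal + p$dG_hydride_kcal)
  tr <- data.frame(
    from = c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x"),
    to   = c("ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x", "i"),
    step_type = c("ET", "ET", "na_binding", "conformational", "na_release",
                  "ET", "na_binding", "conformational", "na_release",
                  "hydride"),
    dG0_kcal = c(p$dG_et_chain_kcal, p$dG_et_chain_kcal,
                 p$dG_bind_reduced_kcal, p$dG_conf_kcal, rem1,
                 p$dG_et_chain_kcal,
                 p$dG_et_chain_kcal + p$dG_bind_reduced_kcal,
                 p$dG_conf_kcal, rem2, p$dG_hydride_kcal),
    electrogenic_fraction = c(0, 0, eg[["uptake"]], eg[["translocation"]],
                              eg[["release"]], 0, eg[["uptake"]],
                              eg[["translocation"]], eg[["release"]], 0),
    na_release = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )

  # forward rates at SMF = 0
  dist <- p$distances_A
  kcal2eV <- .MEV_PER_KCAL / 1000  # kcal/mol -> eV (per charge)
  k_fwd0 <- numeric(nrow(tr))
  for (j in seq_len(nrow(tr))) {
    k_fwd0[j] <- switch(tr$step_type[j],
      ET = {
        d <- switch(tr$from[j],
                    i = dist[["fd_b8"]], vi = dist[["fd_b8"]],
                    ii = dist[["b8_ae1"]], dist[["fmn_chain"]])
        tunneling_rate(d, tr$dG0_kcal[j] * kcal2eV, lambda_eV = p$lambda_eV)
      },
      na_binding = eyring_rate(p$barrier_binding_kcal, p$temperature_K),
      conformational = eyring_rate(p$barrier_conf_reduced_kcal,
                                   p$temperature_K),
      na_release = tunneling_rate(dist[["ae1_fmng"]],
                                  tr$dG0_kcal[j] * kcal2eV,
                                  lambda_eV = p$lambda_eV),
      hydride = eyring_rate(p$barrier_hydride_kcal, p$temperature_K)
    )
  }
  tr$k_fwd0 <- k_fwd0

  model <- structure(
    list(states = states, transitions = tr,
         thermo = pump_thermo(p$smf_mV, p$temperature_K,
                              na_per_electron = p$na_per_cycle / 2),
         params = p),
    class = c("pump_cycle_model", "markov_model")
  )
  resid <- cycle_closure_check(model)
  if (abs(resid) > closure_tol) {
    stop(sprintf("cycle closure violated: residual %.3g kcal/mol", resid),
         call. = FALSE)
  }
  model
}

#' @export
print.pump_cycle_model <- function(x, ...) {
  cat(sprintf("<pump_cycle_model> %d states, %d transitions, SMF = %g mV\n",
              nrow(x$states), nrow(x$transitions), x$thermo$smf_mV))
  invisible(x)
}

#' Define a generic continuous-time Markov model
#'
#' A minimal state-transition model usable by [rate_matrix()],
#' [steady_state()] and [simulate_timecourse()] — handy for small
#' analytically solvable systems. Reverse rates imply step free energies
#' via detailed balance, \eqn{\Delta G = RT \ln(k_{rev}/k_{fwd})}.
#'
#' @param labels Character vector of state labels.
#' @param from,to Character vectors of transition endpoints.
#' @param k_fwd,k_rev Forward and reverse rates (s^-1; `k_rev` may be 0
#'   for an irreversible step, represented by a negligible floor rate).
#' @param temperature_K Temperature used for the implied free energies.
#' @return An object of class `markov_model`.
#' @examples
#' m <- markov_model(c("1", "2"), from = "1", to = "2",
#'                   k_fwd = 2, k_rev = 1)
#' steady_state(m)$populations  # 1/3, 2/3
#' @export
markov_model <- function(labels, from, to, k_fwd, k_rev,
                         temperature_K = .DEFAULT_T_K) {
  stopifnot(length(from) == length(to), length(k_fwd) == length(from),
            length(k_rev) == length(from), all(k_fwd > 0),
            all(c(from, to) %in% labels))
  rt <- .rt_kcal(temperature_K)
  k_rev <- pmax(k_rev, 1e-300)
  tr <- data.frame(from = from, to = to, step_type = "generic",
                   dG0_kcal = rt * log(k_rev / k_fwd),
                   electrogenic_fraction = 0,
                   na_release = 0L, k_fwd0 = k_fwd,
                   stringsAsFactors = FALSE)
  structure(
    list(states = data.frame(label = labels, stringsAsFactors = FALSE),
         transitions = tr, thermo = pump_thermo(0, temperature_K, 0),
         params = list(na_per_cycle = 0)),
    class = "markov_model"
  )
}

# per-transition forward/backward rates at a given SMF. The SMF shifts each
# step's free energy by electrogenic_fraction * F * V and the shift is split
# symmetrically between the forward and backward rate (factor 1/2).
.transition_rates <- function(model, smf_mV = model$thermo$smf_mV) {
  tr <- model$transitions
  rt <- .rt_kcal(model$thermo$temperature_K)
  dG_smf <- tr$electrogenic_fraction * .FARADAY_KCAL * smf_mV / 1000
  dG <- tr$dG0_kcal + dG_smf
  k_fwd <- tr$k_fwd0 * exp(-0.5 * dG_smf / rt)
  k_rev <- k_fwd * exp(dG / rt)
  data.frame(from = tr$from, to = tr$to, dG_kcal = dG,
             k_fwd = k_fwd, k_rev = k_rev,
             na_release = tr$na_release, stringsAsFactors = FALSE)
}

#' Master-equation generator matrix
#'
#' Builds the column-stochastic generator K of the model at its SMF:
#' off-diagonal `K[j, i]` is the rate from state i to state j (forward
#' rates plus detailed-balance reverse rates, both SMF-adjusted), and each
#' diagonal makes its column sum to zero, so that dp/dt = K p conserves
#' total population.
#'
#' @param model A `pump_cycle_model`.
#' @param smf_mV Optional SMF override (mV).
#' @return A square matrix with state labels as dimnames.
#' @export
rate_matrix <- function(model, smf_mV = model$thermo$smf_mV) {
  stopifnot(inherits(model, "markov_model"))
  labs <- model$states$label
  n <- length(labs)
  K <- matrix(0, n, n, dimnames = list(labs, labs))
  rts <- .transition_rates(model, smf_mV)
  if (any(!is.finite(rts$k_fwd)) || any(!is.finite(rts$k_rev))) {
    stop("non-finite transition rates", call. = FALSE)
  }
  for (j in seq_len(nrow(rts))) {
    a <- rts$from[j]; b <- rts$to[j]
    K[b, a] <- K[b, a] + rts$k_fwd[j]
    K[a, b] <- K[a, b] + rts$k_rev[j]
  }
  g <- igraph::graph_from_adjacency_matrix(K > 0, mode = "directed")
  if (!igraph::is_connected(g, mode = "strong")) {
    stop("transition graph is not strongly connected", call. = FALSE)
  }
  diag(K) <- diag(K) - colSums(K)
  K
}

#' Steady state and pumping flux
#'
#' Solves the null space of the generator (smallest singular vector),
#' normalizes it to a probability distribution, and computes the net cycle
#' flux across every transition; at steady state all edge cuts agree. The
#' Na+ flux is `na_per_cycle` times the cycle flux and the NADH production
#' flux equals the cycle flux (one NADH per 2-electron cycle).
#'
#' @inheritParams rate_matrix
#' @param tol Residual tolerance on `K p = 0`.
#' @return A list of class `flux_result`: `populations` (named, sums to 1),
#'   `cycle_flux`, `na_flux`, `nadh_flux` (s^-1), and `edge_flux`.
#' @export
steady_state <- function(model, smf_mV = model$thermo$smf_mV, tol = 1e-10) {
  K <- rate_matrix(model, smf_mV)
  sv <- svd(K)
  d <- sv$d
  if (sum(d < max(d) * 1e-9) > 1L) {
    stop("degenerate null space: steady state is not unique", call. = FALSE)
  }
  p <- sv$v[, ncol(K)]
  p <- p / sum(p)
  if (any(p < -1e-9)) stop("negative steady-state population", call. = FALSE)
  p <- pmax(p, 0); p <- p / sum(p)
  resid <- max(abs(K %*% p))
  if (resid > tol * max(abs(K))) {
    stop(sprintf("steady-state residual too large: %.3g", resid),
         call. = FALSE)
  }
  names(p) <- model$states$label
  rts <- .transition_rates(model, smf_mV)
  edge_flux <- p[rts$from] * rts$k_fwd - p[rts$to] * rts$k_rev
  names(edge_flux) <- paste(rts$from, rts$to, sep = "->")
  cycle_flux <- unname(edge_flux[length(edge_flux)])  # closing edge cut
  na_per_cycle <- model$params$na_per_cycle
  structure(
    list(populations = p, cycle_flux = cycle_flux,
         na_flux = na_per_cycle * cycle_flux, nadh_flux = cycle_flux,
         edge_flux = edge_flux, smf_mV = smf_mV),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf(
    "<flux_result> SMF %g mV: cycle %.4g /s, Na+ %.4g /s, NADH %.4g /s\n",
    x$smf_mV, x$cycle_flux, x$na_flux, x$nadh_flux))
  invisible(x)
}

#' Time course of the pumping cycle
#'
#' Propagates the master equation either deterministically (stiff ODE
#' integration of dp/dt = K p) or stochastically (exact event-driven
#' Gillespie sampling of single trajectories), tracking cumulative Na+
#' released to the periplasm. Both converge to [steady_state()] populations
#' at long times.
#'
#' @inheritParams rate_matrix
#' @param t_end Final time in seconds (> 0; 0 returns the initial state).
#' @param method `"deterministic"` or `"stochastic"`.
#' @param p0 Initial populations (default: all in state "i").
#' @param n_out Number of output time points (deterministic path).
#' @param n_traj Number of stochastic trajectories to average.
#' @param seed Integer seed, required for the stochastic path.
#' @param max_events Per-trajectory event cap for the stochastic sampler
#'   (exceeding it is an error: exact sampling of very stiff models over
#'   long horizons is intentionally refused rather than silently
#'   truncated).
#' @return For the deterministic path, a list with `times`, `populations`
#'   (time x state matrix) and cumulative `na_pumped`. For the stochastic
#'   path, the per-trajectory time-averaged occupancies, the end-time
#'   state distribution `p_final` (comparable to the deterministic
#'   `populations` row at `t_end`), and the per-trajectory Na+ counts.
#' @export
simulate_timecourse <- function(model, t_end,
                                method = c("deterministic", "stochastic"),
                                p0 = NULL, n_out = 200, n_traj = 100,
                                seed = NULL, max_events = 1e6,
                                smf_mV = model$thermo$smf_mV) {
  method <- match.arg(method)
  stopifnot(inherits(model, "markov_model"), t_end >= 0)
  labs <- model$states$label
  n <- length(labs)
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1))
  stopifnot(length(p0) == n, all(p0 >= 0), abs(sum(p0) - 1) < 1e-9)
  if (t_end == 0) {
    return(list(times = 0,
                populations = matrix(p0, 1, n, dimnames = list(NULL, labs)),
                na_pumped = 0, method = method))
  }
  K <- rate_matrix(model, smf_mV)
  rts <- .transition_rates(model, smf_mV)

  if (method == "deterministic") {
    times <- seq(0, t_end, length.out = n_out)
    deriv <- function(t, y, parms) {
      p <- y[1:n]
      rel <- rts$na_release == 1L
      jrel <- sum(p[match(rts$from[rel], labs)] * rts$k_fwd[rel] -
                    p[match(rts$to[rel], labs)] * rts$k_rev[rel])
      list(c(as.vector(K %*% p), jrel))
    }
    out <- deSolve::ode(y = c(p0, 0), times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-12)
    pops <- out[, 2:(n + 1), drop = FALSE]
    colnames(pops) <- labs
    return(list(times = out[, 1], populations = pops,
                na_pumped = out[, n + 2], method = method))
  }

  if (is.null(seed)) stop("stochastic simulation requires a seed",
                          call. = FALSE)
  set.seed(seed)
  # event table: state index -> possible jumps with rates
  ev_from <- c(match(rts$from, labs), match(rts$to, labs))
  ev_to <- c(match(rts$to, labs), match(rts$from, labs))
  ev_rate <- c(rts$k_fwd, rts$k_rev)
  ev_na <- c(rts$na_release, -rts$na_release)
  by_state <- split(seq_along(ev_from), ev_from)
  tot_rate <- vapply(seq_len(n), function(s) {
    idx <- by_state[[as.character(s)]]
    if (is.null(idx)) 0 else sum(ev_rate[idx])
  }, numeric(1))
  occ_time <- matrix(0, n_traj, n, dimnames = list(NULL, labs))
  final_state <- integer(n_traj)
  na_final <- numeric(n_traj)
  for (tr_i in seq_len(n_traj)) {
    s <- sample.int(n, 1, prob = p0)
    t_now <- 0; na <- 0; nev <- 0
    repeat {
      if (tot_rate[s] == 0) {  # absorbing state
        occ_time[tr_i, s] <- occ_time[tr_i, s] + (t_end - t_now)
        t_now <- t_end
        break
      }
      dt <- stats::rexp(1, tot_rate[s])
      if (t_now + dt >= t_end) {
        occ_time[tr_i, s] <- occ_time[tr_i, s] + (t_end - t_now)
        t_now <- t_end
        break
      }
      occ_time[tr_i, s] <- occ_time[tr_i, s] + dt
      t_now <- t_now + dt
      idx <- by_state[[as.character(s)]]
      pick <- idx[sample.int(length(idx), 1, prob = ev_rate[idx])]
      s <- ev_to[pick]
      na <- na + ev_na[pick]
      nev <- nev + 1
      if (nev >= max_events) {
        stop("stochastic trajectory exceeded max_events before t_end; ",
             "reduce t_end or raise max_events", call. = FALSE)
      }
    }
    final_state[tr_i] <- s
    na_final[tr_i] <- na
  }
  p_final <- tabulate(final_state, nbins = n) / n_traj
  names(p_final) <- labs
  list(times = t_end, populations = occ_time / t_end, p_final = p_final,
       na_pumped = mean(na_final), na_pumped_per_traj = na_final,
       method = method, seed = seed)
}

#' Scan steady-state flux against sodium-motive force
#'
#' Recomputes [steady_state()] at each SMF value. The pumping flux is
#' maximal at 0 mV, decreases monotonically with opposing SMF, crosses zero
#' at the break-even SMF of the parameterization, and reverses above it.
#'
#' @inheritParams rate_matrix
#' @param smf_values Numeric vector of SMF values (mV).
#' @return A data frame with columns `smf_mV`, `cycle_flux`, `na_flux`,
#'   `nadh_flux`.
#' @export
smf_scan <- function(model, smf_values) {
  stopifnot(length(smf_values) >= 1)
  rows <- lapply(smf_values, function(v) {
    fr <- steady_state(model, smf_mV = v)
    data.frame(smf_mV = v, cycle_flux = fr$cycle_flux,
               na_flux = fr$na_flux, nadh_flux = fr$nadh_flux)
  })
  do.call(rbind, rows)
}

#' Free-energy profile along the cycle
#'
#' Assembles the cumulative free energy along the ten-step path, with a
#' barrier on each step recovered from its forward rate by inverting the
#' transition-state law, \eqn{\Delta G^\ddagger = RT \ln(k_B T / h / k)}.
#' The endpoint equals the net cycle free energy (reaction free energy plus
#' the SMF work of the pumped charges).
#'
#' @inheritParams rate_matrix
#' @return A data frame of class `free_energy_profile` with one row per
#'   step: `from`, `to`, `dG_step_kcal`, `G_cum_kcal` (after the step), and
#'   `barrier_kcal` (relative to the step's starting state).
#' @export
profile_from_model <- function(model, smf_mV = model$thermo$smf_mV) {
  stopifnot(inherits(model, "pump_cycle_model"))
  rts <- .transition_rates(model, smf_mV)
  path_states <- c(rts$from, rts$to[length(rts$to)])
  if (!identical(sort(unique(rts$from)), sort(model$states$label))) {
    stop("cycle path must cover all states exactly once", call. = FALSE)
  }
  rt <- .rt_kcal(model$thermo$temperature_K)
  pre <- .KB_OVER_H * model$thermo$temperature_K
  barrier <- pmax(rt * log(pre / rts$k_fwd), 0)
  out <- data.frame(from = rts$from, to = rts$to,
                    dG_step_kcal = rts$dG_kcal,
                    G_cum_kcal = cumsum(rts$dG_kcal),
                    barrier_kcal = barrier, stringsAsFactors = FALSE)
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

#' Thermodynamic closure check of the cycle
#'
#' The sum of step free energies around the full cycle must equal the
#' overall reaction free energy plus the electrogenic work
#' `na_per_cycle * F * SMF`; the SMF contribution cancels by construction,
#' so the residual is SMF-invariant. A non-zero residual diagnoses an
#' inconsistent parameter set.
#'
#' @inheritParams rate_matrix
#' @return Residual in kcal/mol (should be ~0).
#' @export
cycle_closure_check <- function(model, smf_mV = model$thermo$smf_mV) {
  stopifnot(inherits(model, "pump_cycle_model"))
  p <- model$params
  dG_rxn <- -2 * .FARADAY_KCAL * (p$nad_mV - p$fd_mV) / 1000
  rts <- .transition_rates(model, smf_mV)
  sum(rts$dG_kcal) -
    (dG_rxn + p$na_per_cycle * .FARADAY_KCAL * smf_mV / 1000)
}
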