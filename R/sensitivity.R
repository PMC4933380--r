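# Forward-sensitivity simulation and the dynamical-influence score.
#
# The influence kappa_i of rate constant k_i is defined through
#   kappa_i^2 = sum_c sum_y (1/T_c) int_0^{T_c}
#                 [ dy_c(t)/dk_i * k_i / y_max ]^2 dt,
# with y_c(t) the trajectory of species y under stimulation condition c,
# evaluated at the reference rate constants k*, and y_max the maximum of y
# over ALL conditions jointly. The k_i / y_max normalization makes the
# integrand a log-derivative in k scaled to each species' dynamic range, so
# kappa is invariant under unit changes of either k_i or any concentration.

# Symbolic compilation of a network: stoichiometry matrix plus derivative
# expressions of each rate law with respect to species and rate constants.
compile_network <- function(net, k_ids) {
  sp_ids <- net$species$id
  n_sp <- length(sp_ids)
  n_rx <- length(net$reactions)
  N <- matrix(0, n_sp, n_rx, dimnames = list(sp_ids, NULL))
  rate_exprs <- vector("list", n_rx)
  drate_dy <- vector("list", n_rx)   # each: named list over species
  drate_dk <- vector("list", n_rx)   # each: named list over rate constants
  for (j in seq_len(n_rx)) {
    rx <- net$reactions[[j]]
    N[names(rx$stoich), j] <- rx$stoich
    ex <- parse_rate_law(rx$rate, rx$id)
    rate_exprs[[j]] <- ex
    vars <- all.vars(ex)
    drate_dy[[j]] <- lapply(stats::setNames(nm = intersect(sp_ids, vars)),
                            function(v) stats::D(ex, v))
    drate_dk[[j]] <- lapply(stats::setNames(nm = intersect(k_ids, vars)),
                            function(v) stats::D(ex, v))
  }
  list(N = N, rate_exprs = rate_exprs, drate_dy = drate_dy,
       drate_dk = drate_dk, sp_ids = sp_ids, k_ids = k_ids)
}

#' Simulate a network with forward parameter sensitivities
#'
#' Integrates the species trajectories together with the first-order
#' sensitivities `dy/dk` of every species to every rate constant, by solving
#' the forward sensitivity system (state Jacobian times sensitivity matrix
#' plus the direct parameter derivative of the vector field) alongside the
#' state, on a uniform time grid over the condition's horizon.
#'
#' @param net A `reaction_network`.
#' @param cond A `stimulation_condition`; its overrides are applied before
#'   integration.
#' @param n_grid Number of grid intervals (>= 16); output has `n_grid + 1`
#'   time points.
#' @param rtol,atol Integrator tolerances; `atol` defaults to
#'   `1e-10 * max(1, max(initial concentrations))`.
#' @param sensitivities If `FALSE`, only the state is integrated (used for
#'   finite-perturbation runs).
#' @return A `sensitivity_trajectory`: list with `condition_id`, `times`,
#'   `y` (time x species matrix), `sens` (time x species x rate-constant
#'   array, or `NULL`), `k` (named rate-constant values used) and `horizon`.
#' @export
simulate_with_sensitivities <- function(net, cond, n_grid = 512,
                                        rtol = 1e-8, atol = NULL,
                                        sensitivities = TRUE) {
  stopifnot(inherits(net, "reaction_network"),
            inherits(cond, "stimulation_condition"))
  if (n_grid < 16) stop("n_grid must be >= 16")
  net <- apply_condition(net, cond)
  sp_ids <- net$species$id
  k_sel <- net$parameters$rate_constant
  k_ids <- net$parameters$id[k_sel]
  k_vals <- stats::setNames(net$parameters$value[k_sel], k_ids)
  n_sp <- length(sp_ids)
  n_k <- length(k_ids)
  comp <- compile_network(net, k_ids)
  if (is.null(atol)) atol <- 1e-10 * max(1, net$species$initial)

  env <- initial_state_env(net)
  n_rx <- length(net$reactions)
  eval_field <- function(y) {
    for (i in seq_len(n_sp)) assign(sp_ids[i], y[i], envir = env)
    r <- vapply(comp$rate_exprs, eval, numeric(1), envir = env)
    dydt <- drop(comp$N %*% r)
    Jy <- NULL; Jk <- NULL
    if (sensitivities) {
      Ry <- matrix(0, n_rx, n_sp, dimnames = list(NULL, sp_ids))
      Rk <- matrix(0, n_rx, n_k, dimnames = list(NULL, k_ids))
      for (j in seq_len(n_rx)) {
        for (v in names(comp$drate_dy[[j]]))
          Ry[j, v] <- eval(comp$drate_dy[[j]][[v]], env)
        for (v in names(comp$drate_dk[[j]]))
          Rk[j, v] <- eval(comp$drate_dk[[j]][[v]], env)
      }
      Jy <- comp$N %*% Ry
      Jk <- comp$N %*% Rk
    }
    list(dydt = dydt, Jy = Jy, Jk = Jk)
  }

  y0 <- net$species$initial
  state0 <- if (sensitivities && n_k > 0)
    c(y0, numeric(n_sp * n_k)) else y0
  deriv <- function(t, state, parms) {
    y <- state[seq_len(n_sp)]
    f <- eval_field(y)
    if (sensitivities && n_k > 0) {
      S <- matrix(state[-seq_len(n_sp)], n_sp, n_k)
      dS <- f$Jy %*% S + f$Jk
      list(c(f$dydt, as.vector(dS)))
    } else list(f$dydt)
  }
  times <- seq(0, cond$horizon, length.out = n_grid + 1)
  sol <- tryCatch(
    deSolve::lsoda(state0, times, deriv, parms = NULL,
                   rtol = rtol, atol = atol),
    error = function(e) stop("integration failure in condition '",
                             cond$condition_id, "': ", conditionMessage(e))
  )
  if (nrow(sol) < length(times) || any(!is.finite(sol)))
    stop("integration failure in condition '", cond$condition_id,
         "': non-finite state or early termination (stiffness/blow-up?)")
  y <- sol[, 1 + seq_len(n_sp), drop = FALSE]
  colnames(y) <- sp_ids
  sens <- NULL
  if (sensitivities && n_k > 0) {
    sens <- array(sol[, (1 + n_sp) + seq_len(n_sp * n_k), drop = FALSE],
                  dim = c(length(times), n_sp, n_k),
                  dimnames = list(NULL, sp_ids, k_ids))
  } else if (sensitivities) {
    sens <- array(0, dim = c(length(times), n_sp, 0),
                  dimnames = list(NULL, sp_ids, NULL))
  }
  structure(list(condition_id = cond$condition_id, times = times, y = y,
                 sens = sens, k = k_vals, horizon = cond$horizon),
            class = "sensitivity_trajectory")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# Per-species maxima over all conditions jointly (the y_max normalization).
species_maxima <- function(trajs) {
  sp_ids <- colnames(trajs[[1]]$y)
  ymax <- stats::setNames(numeric(length(sp_ids)), sp_ids)
  for (tr in trajs) ymax <- pmax(ymax, apply(tr$y, 2, max))
  ymax
}

#' Dynamical influence of each rate constant
#'
#' Computes the per-rate-constant influence `kappa_i` from stored sensitivity
#' trajectories: the squared, `k_i / y_max`-normalized sensitivities are
#' integrated over each condition's horizon with the trapezoid rule on the
#' stored grid, time-averaged by `1/T_c`, summed over species and conditions,
#' and square-rooted. Species whose maximum over all conditions is zero never
#' move, so their normalization is undefined; they contribute zero. Rate
#' constants with reference value zero score zero (the `k_i` factor
#' annihilates the integrand) and are reported via a message.
#'
#' @param trajs List of `sensitivity_trajectory` objects, one per
#'   stimulation condition (all conditions of the study design).
#' @param net The `reaction_network` the trajectories came from.
#' @param species `"full"` to sum over every species, or a character vector
#'   of species ids restricting the sum (the key-species variant); `y_max`
#'   is always taken over all conditions.
#' @return An `influence_table`: data frame with columns `param_id`, `kappa`,
#'   and attributes `model_id`, `species_used`, `method`, `n_conditions`,
#'   `y_max`.
#' @export
parameter_influence <- function(trajs, net, species = "full") {
  stopifnot(length(trajs) >= 1,
            all(vapply(trajs, inherits, logical(1), "sensitivity_trajectory")))
  if (is.null(trajs[[1]]$sens))
    stop("trajectories were simulated without sensitivities")
  sp_ids <- colnames(trajs[[1]]$y)
  for (tr in trajs)
    if (!identical(colnames(tr$y), sp_ids))
      stop("mismatched species across trajectories")
  subset_ids <- if (identical(species, "full")) sp_ids else {
    unknown <- setdiff(species, sp_ids)
    if (length(unknown)) stop("unknown species id(s): ",
                              paste(unknown, collapse = ", "))
    if (!length(species)) stop("species subset must be nonempty")
    species
  }
  k_ids <- dimnames(trajs[[1]]$sens)[[3]]
  ymax <- species_maxima(trajs)
  live <- subset_ids[ymax[subset_ids] > 0]
  kappa2 <- stats::setNames(numeric(length(k_ids)), k_ids)
  for (tr in trajs) {
    Tc <- tr$horizon
    for (ki in k_ids) {
      kval <- tr$k[[ki]]
      if (kval == 0) next
      acc <- 0
      for (s in live) {
        f <- (tr$sens[, s, ki] * kval / ymax[[s]])^2
        acc <- acc + trapz(tr$times, f)
      }
      kappa2[ki] <- kappa2[ki] + acc / Tc
    }
  }
  zero_k <- k_ids[vapply(k_ids, function(ki)
    any(vapply(trajs, function(tr) tr$k[[ki]] == 0, logical(1))), logical(1))]
  if (length(zero_k))
    message("rate constant(s) with reference value 0 scored as kappa = 0: ",
            paste(zero_k, collapse = ", "))
  out <- data.frame(param_id = k_ids, kappa = sqrt(kappa2),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            model_id = net$model_id,
            species_used = if (identical(species, "full")) "full" else "key",
            method = "differential",
            n_conditions = length(trajs),
            y_max = ymax,
            class = c("influence_table", "data.frame"))
}

#' Influence restricted to key species
#'
#' Recomputes the influence summing only over a stated subset of species —
#' the species the model's original authors considered most important —
#' while `y_max` remains the per-species maximum over all conditions.
#' Passing the full species set reproduces [parameter_influence()] exactly.
#'
#' @param trajs List of `sensitivity_trajectory` objects.
#' @param net The `reaction_network`.
#' @param key_species Nonempty character vector of declared species ids.
#' @return An `influence_table` with `species_used = "key"`.
#' @export
restrict_to_key_species <- function(trajs, net, key_species) {
  if (!length(key_species)) stop("key_species must be nonempty")
  parameter_influence(trajs, net, species = key_species)
}

#' Dynamical influence from finite rate-constant perturbations
#'
#' The finite-perturbation variant replaces the differential sensitivity
#' `dy/dk` with the central difference
#' `[y(k(1 + delta)) - y(k(1 - delta))] / (2 delta k)`, perturbing one rate
#' constant at a time and re-simulating every condition. With the default
#' `delta = 0.25` this probes mutations of moderate effect; as `delta -> 0`
#' it converges to the differential influence. `y_max` is taken from the
#' unperturbed reference runs.
#'
#' @param net A `reaction_network`.
#' @param conds List of `stimulation_condition` objects.
#' @param delta Fractional perturbation (default 0.25).
#' @param n_grid Grid intervals per condition.
#' @param species `"full"` or a character vector of species ids.
#' @return An `influence_table` with `method = "finite"`.
#' @export
finite_perturbation_influence <- function(net, conds, delta = 0.25,
                                          n_grid = 512, species = "full") {
  stopifnot(inherits(net, "reaction_network"), length(conds) >= 1)
  k_sel <- net$parameters$rate_constant
  k_ids <- net$parameters$id[k_sel]
  base <- lapply(conds, function(cd)
    simulate_with_sensitivities(net, cd, n_grid = n_grid,
                                sensitivities = FALSE))
  sp_ids <- colnames(base[[1]]$y)
  subset_ids <- if (identical(species, "full")) sp_ids else {
    unknown <- setdiff(species, sp_ids)
    if (length(unknown)) stop("unknown species id(s): ",
                              paste(unknown, collapse = ", "))
    species
  }
  ymax <- species_maxima(base)
  live <- subset_ids[ymax[subset_ids] > 0]
  kappa2 <- stats::setNames(numeric(length(k_ids)), k_ids)
  for (ki in k_ids) {
    kval <- net$parameters$value[net$parameters$id == ki]
    if (kval == 0) {
      message("rate constant '", ki, "' has reference value 0; kappa = 0")
      next
    }
    pert <- function(fac) {
      nn <- net
      nn$parameters$value[nn$parameters$id == ki] <- kval * fac
      lapply(conds, function(cd)
        simulate_with_sensitivities(nn, cd, n_grid = n_grid,
                                    sensitivities = FALSE))
    }
    up <- pert(1 + delta)
    dn <- pert(1 - delta)
    for (ci in seq_along(conds)) {
      tr <- base[[ci]]
      dydk <- (up[[ci]]$y - dn[[ci]]$y) / (2 * delta * kval)
      acc <- 0
      for (s in live)
        acc <- acc + trapz(tr$times, (dydk[, s] * kval / ymax[[s]])^2)
      kappa2[ki] <- kappa2[ki] + acc / tr$horizon
    }
  }
  out <- data.frame(param_id = k_ids, kappa = sqrt(kappa2),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            model_id = net$model_id,
            species_used = if (identical(species, "full")) "full" else "key",
            method = sprintf("finite+/-%g", delta),
            n_conditions = length(conds),
            y_max = ymax,
            class = c("influence_table", "data.frame"))
}

#' Simulate all conditions of a study design with sensitivities
#'
#' Convenience wrapper running [simulate_with_sensitivities()] for each
#' stimulation condition.
#'
#' @param net A `reaction_network`.
#' @param conds List of `stimulation_condition` objects.
#' @param n_grid Grid intervals per condition.
#' @param ... Passed to [simulate_with_sensitivities()].
#' @return List of `sensitivity_trajectory` objects.
#' @export
simulate_conditions <- function(net, conds, n_grid = 512, ...) {
  lapply(conds, function(cd)
    simulate_with_sensitivities(net, cd, n_grid = n_grid, ...))
}
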