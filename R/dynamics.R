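#' Per-node dynamical parameters
#'
#' Sigmoid gain `h` and first-order decay rate `gamma` for every node.
#' Defaults `h = 10`, `gamma = 1` give a smooth sigmoidal response and unit
#' decay, the standard choice for this class of normalized regulatory models;
#' edge weights (activator alpha, inhibitor beta) live on the edges and
#' default to 1.
#'
#' @param net a `regnet`
#' @param h positive scalar or per-node vector of sigmoid gains
#' @param gamma positive scalar or per-node vector of decay rates
#' @param source_policy how nodes without regulators evolve: `"hold"` keeps
#'   them at their initial value (boundary inputs, the default), `"decay"`
#'   lets them decay to 0
#' @return object of class `node_params`
#' @export
node_params <- function(net, h = 10, gamma = 1,
                        source_policy = c("hold", "decay")) {
  stopifnot(inherits(net, "regnet"))
  source_policy <- match.arg(source_policy)
  n <- n_nodes(net)
  h <- rep_len(h, n); gamma <- rep_len(gamma, n)
  if (any(h <= 0) || any(gamma <= 0)) stop("h and gamma must be > 0")
  structure(list(h = stats::setNames(h, net$nodes$id),
                 gamma = stats::setNames(gamma, net$nodes$id),
                 source_policy = source_policy),
            class = "node_params")
}

#' Solver configuration
#'
#' @param method `"rk4_fixed"` (classical fixed-step RK4, the default and
#'   reference method) or `"adaptive"` (Cash-Karp RK45 with step control,
#'   kept as an independent cross-check)
#' @param step fixed RK4 step (model-time units)
#' @param tol convergence tolerance on `max |dx/dt|`
#' @param t_max integration horizon; non-convergence by `t_max` is reported,
#'   never raised
#' @param seed default RNG seed for baseline initial conditions
#' @return object of class `solver_config`
#' @export
solver_config <- function(method = c("rk4_fixed", "adaptive"),
                          step = 0.01, tol = 1e-6, t_max = 100, seed = 0) {
  method <- match.arg(method)
  stopifnot(step > 0, tol > 0, t_max > 0, seed >= 0)
  structure(list(method = method, step = step, tol = tol,
                 t_max = t_max, seed = as.integer(seed)),
            class = "solver_config")
}

#' Perturbation specification
#'
#' `initial` overrides the initial condition of named nodes; `clamps` holds
#' named nodes at a fixed value for the whole integration (sustained
#' stimulation or blockade). A node may appear in at most one of the two.
#'
#' @param initial named numeric vector (values in `[0,1]`) or NULL
#' @param clamps named numeric vector (values in `[0,1]`) or NULL
#' @return object of class `perturbation`
#' @export
perturbation <- function(initial = NULL, clamps = NULL) {
  chk <- function(v, what) {
    if (is.null(v)) return(stats::setNames(numeric(), character()))
    v <- unlist(v)
    if (is.null(names(v)) || any(names(v) == ""))
      stop(what, " must be a named vector")
    if (any(v < 0 | v > 1)) stop(what, " values must lie in [0,1]")
    v
  }
  initial <- chk(initial, "initial"); clamps <- chk(clamps, "clamps")
  both <- intersect(names(initial), names(clamps))
  if (length(both) > 0)
    stop("node(s) in both initial and clamps: ", paste(both, collapse = ", "))
  structure(list(initial = initial, clamps = clamps), class = "perturbation")
}

#' Sigmoid activation function
#'
#' The bounded activation response to total input `omega`, with gain `h`:
#' \deqn{\Phi(\omega) = \frac{-e^{0.5h} + e^{-h(\omega - 0.5)}}
#'   {(1 - e^{0.5h})(1 + e^{-h(\omega - 0.5)})}}
#' Strictly increasing on `[0,1]` with exact anchors
#' \eqn{\Phi(0)=0, \Phi(0.5)=0.5, \Phi(1)=1} (algebraic cancelation, not
#' numerical coincidence).
#'
#' @param omega total input in `[0,1]` (vectorized)
#' @param h positive gain
#' @return activation value(s) in `[0,1]`
#' @export
activation <- function(omega, h = 10) {
  if (any(h <= 0)) stop("h must be > 0")
  eps <- 1e-9
  if (any(omega < -eps | omega > 1 + eps))
    stop("omega outside [0,1]: ", paste(omega[omega < -eps | omega > 1 + eps], collapse = ", "))
  omega <- pmin(pmax(omega, 0), 1)
  a <- exp(0.5 * h)
  e <- exp(-h * (omega - 0.5))
  (-a + e) / ((1 - a) * (1 + e))
}

#' Total regulatory input to a node
#'
#' Combines the activation levels of a node's activators and inhibitors into
#' a single normalized input \eqn{\omega \in [0,1]}. With activator weights
#' \eqn{\alpha_p} and activator levels \eqn{x^a_p}, the activator block is
#' \deqn{A = \frac{1+\sum\alpha}{\sum\alpha}\cdot
#'   \frac{\sum\alpha x^a}{1+\sum\alpha x^a},}
#' the inhibitor block \eqn{I} is analogous; a node with both gets
#' \eqn{\omega = A(1-I)}, activators only \eqn{\omega = A}, inhibitors only
#' \eqn{\omega = 1-I}. Saturation identities: a single activator at 1 gives
#' \eqn{\omega = 1} for any weight; a single inhibitor at 1 gives 0.
#'
#' @param node node id
#' @param state named numeric vector of activation levels in `[0,1]`
#' @param net a `regnet`
#' @return scalar omega in `[0,1]`
#' @export
total_input <- function(node, state, net) {
  stopifnot(inherits(net, "regnet"))
  e <- net$edges
  act <- e[e$target == node & e$sign == "activation", , drop = FALSE]
  inh <- e[e$target == node & e$sign == "inhibition", , drop = FALSE]
  if (nrow(act) + nrow(inh) == 0)
    stop("node '", node, "' has no incoming edges; total_input is undefined for source nodes")
  xs <- state[c(act$source, inh$source)]
  if (anyNA(xs)) stop("state missing regulator(s) of '", node, "'")
  if (any(xs < 0 | xs > 1)) stop("regulator activations must lie in [0,1]")
  block <- function(w, x) {
    sw <- sum(w); swx <- sum(w * x)
    ((1 + sw) / sw) * (swx / (1 + swx))
  }
  if (nrow(act) > 0 && nrow(inh) > 0) {
    A <- block(act$weight, state[act$source])
    I <- block(inh$weight, state[inh$source])
    omega <- A * (1 - I)
  } else if (nrow(act) > 0) {
    omega <- block(act$weight, state[act$source])
  } else {
    omega <- 1 - block(inh$weight, state[inh$source])
  }
  unname(pmin(pmax(omega, 0), 1))
}

# Compile a regnet + params + perturbation into the matrix form the
# integrators consume. kind: 0 regulated, 1 clamped, 2 source.
build_system <- function(net, params, pert = perturbation(), default_initial = 0) {
  ids <- net$nodes$id
  n <- length(ids)
  unknown <- setdiff(c(names(pert$initial), names(pert$clamps)), ids)
  if (length(unknown) > 0)
    stop("perturbation names unknown node(s): ", paste(unknown, collapse = ", "))
  e <- net$edges
  wact <- matrix(0, n, n, dimnames = list(ids, ids))
  winh <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(e))) {
    if (e$sign[k] == "activation")
      wact[e$target[k], e$source[k]] <- wact[e$target[k], e$source[k]] + e$weight[k]
    else
      winh[e$target[k], e$source[k]] <- winh[e$target[k], e$source[k]] + e$weight[k]
  }
  kind <- integer(n)
  kind[rowSums(wact) + rowSums(winh) == 0] <- 2L
  clampv <- numeric(n)
  ci <- match(names(pert$clamps), ids)
  kind[ci] <- 1L; clampv[ci] <- unname(pert$clamps)
  x0 <- rep(default_initial, n)
  x0[match(names(pert$initial), ids)] <- unname(pert$initial)
  x0[ci] <- clampv[ci]
  list(ids = ids, wact = wact, winh = winh,
       h = unname(params$h[ids]), gamma = unname(params$gamma[ids]),
       kind = kind, clamp_value = clampv,
       source_decay = params$source_policy == "decay", x0 = x0)
}

# Precompile the weight matrices and parameter vectors for a fixed network so
# repeated integrations under different perturbations skip the per-call edge
# loop. Numerically identical to integrate_to_steady_state().
compile_system <- function(net, params) {
  sys <- build_system(net, params)
  sys$kind0 <- sys$kind
  sys
}

steady_state_compiled <- function(sys, pert, solver, default_initial = 0) {
  ids <- sys$ids
  kind <- sys$kind0
  clampv <- numeric(length(ids))
  ci <- match(names(pert$clamps), ids)
  if (anyNA(ci)) stop("perturbation names unknown node(s)")
  kind[ci] <- 1L; clampv[ci] <- unname(pert$clamps)
  x0 <- rep(default_initial, length(ids))
  ii <- match(names(pert$initial), ids)
  if (anyNA(ii)) stop("perturbation names unknown node(s)")
  x0[ii] <- unname(pert$initial)
  x0[ci] <- clampv[ci]
  res <- rk4_steady_cpp(sys$wact, sys$winh, sys$h, sys$gamma, kind, clampv,
                        sys$source_decay, x0, solver$step, solver$tol,
                        solver$t_max, clip_tol = 100 * solver$tol)
  structure(list(x_star = stats::setNames(res$x, ids),
                 converged = res$converged, residual = res$residual,
                 t_end = res$t_end, solver = solver),
            class = "steady_state")
}

baseline_compiled <- function(sys, seed, solver) {
  x0 <- with_preserved_rng({
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
    stats::runif(length(sys$ids))
  })
  steady_state_compiled(sys, perturbation(initial = stats::setNames(x0, sys$ids)),
                        solver)
}

#' System right-hand side
#'
#' Derivative of every node at the given state: for an unclamped regulated
#' node, \eqn{dx_n/dt = \Phi(\omega_n) - \gamma_n x_n}; clamped nodes have
#' zero derivative; source nodes follow the source-node policy (`"hold"`:
#' zero; `"decay"`: \eqn{-\gamma_n x_n}).
#'
#' @param state named numeric vector in `[0,1]`
#' @param net a `regnet`
#' @param params `node_params`
#' @param clamps named numeric vector of clamped nodes (or NULL)
#' @return named derivative vector
#' @export
rhs <- function(state, net, params, clamps = NULL) {
  pert <- perturbation(clamps = clamps)
  sys <- build_system(net, params, pert)
  x <- state[sys$ids]
  if (anyNA(x)) stop("state must cover all nodes")
  dx <- deriv_cpp(sys$wact, sys$winh, sys$h, sys$gamma, sys$kind,
                  sys$source_decay, unname(x))
  stats::setNames(dx, sys$ids)
}

# Pure-R Cash-Karp RK45 with adaptive step, pinning clamps each step.
# Independent of the C++ path; used for solver cross-validation.
rk45_steady_r <- function(sys, solver) {
  f <- function(x) deriv_cpp_r(sys, x)
  x <- sys$x0
  ci <- which(sys$kind == 1L)
  x[ci] <- sys$clamp_value[ci]
  t <- 0; dt <- solver$step
  atol <- 1e-9
  repeat {
    k1 <- f(x)
    resid <- max(abs(k1))
    if (resid <= solver$tol) return(list(x = x, converged = TRUE, residual = resid, t_end = t))
    if (t >= solver$t_max) return(list(x = x, converged = FALSE, residual = resid, t_end = t))
    dt <- min(dt, solver$t_max - t)
    # Cash-Karp tableau
    k2 <- f(x + dt * (k1 / 5))
    k3 <- f(x + dt * (3 * k1 + 9 * k2) / 40)
    k4 <- f(x + dt * (3 * k1 / 10 - 9 * k2 / 10 + 6 * k3 / 5))
    k5 <- f(x + dt * (-11 * k1 / 54 + 5 * k2 / 2 - 70 * k3 / 27 + 35 * k4 / 27))
    k6 <- f(x + dt * (1631 * k1 / 55296 + 175 * k2 / 512 + 575 * k3 / 13824 +
                        44275 * k4 / 110592 + 253 * k5 / 4096))
    x5 <- x + dt * (37 * k1 / 378 + 250 * k3 / 621 + 125 * k4 / 594 + 512 * k6 / 1771)
    x4 <- x + dt * (2825 * k1 / 27648 + 18575 * k3 / 48384 + 13525 * k4 / 55296 +
                      277 * k5 / 14336 + k6 / 4)
    err <- max(abs(x5 - x4))
    if (err <= atol || dt <= 1e-6) {
      x <- pmin(pmax(x5, 0), 1)
      x[ci] <- sys$clamp_value[ci]
      if (any(!is.finite(x)))
        stop("integration error: non-finite state at node ",
             sys$ids[which(!is.finite(x))[1]])
      t <- t + dt
      dt <- min(dt * min(5, max(1, 0.9 * (atol / max(err, 1e-300))^0.2)), 1)
    } else {
      dt <- max(dt * max(0.2, 0.9 * (atol / err)^0.25), 1e-6)
    }
  }
}

deriv_cpp_r <- function(sys, x) {
  deriv_cpp(sys$wact, sys$winh, sys$h, sys$gamma, sys$kind, sys$source_decay, x)
}

#' Integrate the network to a steady state
#'
#' Runs the clamped ODE system from an initial condition until
#' `max |dx/dt| <= tol` (converged) or `t >= t_max` (reported with
#' `converged = FALSE`, never an exception). Nodes not named in
#' `perturbation$initial` start at `default_initial` (0 by default); clamped
#' nodes equal their clamp value at every step; all states are clipped to
#' `[0,1]` after each step.
#'
#' @param net a `regnet`
#' @param params `node_params`
#' @param pert a `perturbation` (default: none)
#' @param solver a `solver_config`
#' @param default_initial initial value for unnamed nodes, in `[0,1]`
#' @return object of class `steady_state`: `x_star` (named vector),
#'   `converged`, `residual`, `t_end`
#' @export
integrate_to_steady_state <- function(net, params, pert = perturbation(),
                                      solver = solver_config(),
                                      default_initial = 0) {
  stopifnot(inherits(net, "regnet"), inherits(params, "node_params"),
            inherits(pert, "perturbation"), inherits(solver, "solver_config"),
            default_initial >= 0, default_initial <= 1)
  sys <- build_system(net, params, pert, default_initial)
  res <- if (solver$method == "rk4_fixed") {
    rk4_steady_cpp(sys$wact, sys$winh, sys$h, sys$gamma, sys$kind,
                   sys$clamp_value, sys$source_decay, sys$x0,
                   solver$step, solver$tol, solver$t_max,
                   clip_tol = 100 * solver$tol)
  } else {
    rk45_steady_r(sys, solver)
  }
  structure(list(x_star = stats::setNames(res$x, sys$ids),
                 converged = res$converged, residual = res$residual,
                 t_end = res$t_end, solver = solver),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s, residual %.3g, t_end %.2f)\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$t_end))
  print(round(x$x_star, 4))
  invisible(x)
}

#' Baseline steady state from a seeded random initial condition
#'
#' Draws one initial condition, every node i.i.d. uniform on `[0,1]` from a
#' Mersenne-Twister stream seeded with `seed`, then integrates with no
#' clamps. Deterministic for a fixed seed. The baseline is the reference
#' phenotype that perturbation responses are reported against.
#'
#' @param net a `regnet`
#' @param params `node_params`
#' @param seed non-negative integer seed (default 0)
#' @param solver a `solver_config`
#' @return a `steady_state`
#' @export
baseline <- function(net, params, seed = 0, solver = solver_config()) {
  stopifnot(seed >= 0)
  x0 <- with_preserved_rng({
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
    stats::runif(n_nodes(net))
  })
  pert <- perturbation(initial = stats::setNames(x0, net$nodes$id))
  integrate_to_steady_state(net, params, pert, solver)
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Perturbation response relative to the baseline
#'
#' Computes `x_star(perturbed) - x_star(baseline)` node by node. Both
#' activations live in `[0,1]`, so each response component lies in `[-1,1]`
#' — the same normalization as the cytokine-release datasets the model is
#' scored against.
#'
#' @inheritParams integrate_to_steady_state
#' @param seed seed for the baseline initial condition
#' @return object of class `response_vector`: `delta` (named vector),
#'   `baseline`, `perturbed` (the two `steady_state`s)
#' @export
response <- function(net, params, pert, seed = 0, solver = solver_config()) {
  base <- baseline(net, params, seed, solver)
  per <- integrate_to_steady_state(net, params, pert, solver)
  if (!base$converged || !per$converged) {
    cond <- structure(class = c("chondronet_nonconverged", "error", "condition"),
                      list(message = paste0(
                        "steady state did not converge (baseline: ", base$converged,
                        ", perturbed: ", per$converged, ")"),
                        call = sys.call(), baseline = base, perturbed = per))
    stop(cond)
  }
  structure(list(delta = per$x_star - base$x_star,
                 baseline = base, perturbed = per),
            class = "response_vector")
}

#' Write a steady state or response vector as CSV
#'
#' Two columns `node,value`, preceded by `#`-comment lines recording the
#' solver configuration and seed.
#'
#' @param x a `steady_state` or `response_vector`
#' @param path output path
#' @param seed seed to record in the header comment
#' @return `path`, invisibly
#' @export
write_state_csv <- function(x, path, seed = NA) {
  v <- if (inherits(x, "steady_state")) x$x_star else x$delta
  slv <- if (inherits(x, "steady_state")) x$solver else x$perturbed$solver
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# solver: method=%s step=%g tol=%g t_max=%g; seed=%s",
                     slv$method, slv$step, slv$tol, slv$t_max, seed), con)
  writeLines("node,value", con)
  writeLines(sprintf("%s,%.15g", names(v), v), con)
  invisible(path)
}
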