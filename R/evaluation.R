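resolve_mask <- function(x, mask) {
  n <- length(x)
  if (is.null(mask)) return(rep(FALSE, n))
  if (is.logical(mask)) return(rep_len(mask, n))
  if (is.character(mask)) {
    if (is.null(names(x))) stop("character mask requires named vectors")
    return(names(x) %in% mask)
  }
  if (is.numeric(mask)) return(seq_len(n) %in% mask)
  stop("mask must be logical, character, or index vector")
}

check_pairs <- function(predicted, experimental, mask) {
  if (length(predicted) != length(experimental))
    stop("predicted and experimental must have equal length")
  rng <- range(c(predicted, experimental))
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    stop("values must lie in [-1, 1]")
  keep <- !resolve_mask(predicted, mask)
  if (!any(keep)) stop("undefined metric: all pairs masked")
  keep
}

#' Normalized mean absolute deviation
#'
#' Cumulative error between predicted and measured responses:
#' \deqn{NMAD = \frac{\sum_n |x_n - y_n|/2}{N}} over unmasked pairs. Both
#' vectors live in `[-1,1]`, so NMAD is in `[0,1]`; masked pairs are excluded
#' from both the sum and `N`.
#'
#' @param predicted,experimental numeric vectors in `[-1,1]`
#' @param mask pairs to exclude: logical vector, names (for named input), or
#'   indices; NULL for none
#' @return scalar in `[0,1]`
#' @export
nmad <- function(predicted, experimental, mask = NULL) {
  keep <- check_pairs(predicted, experimental, mask)
  mean(abs(predicted[keep] - experimental[keep]) / 2)
}

#' Normalized root squared error (per data point)
#'
#' For each unmasked pair, \eqn{\sqrt{(x_n - y_n)^2}} divided by the maximum
#' such error over the unmasked set, so every value is in `[0,1]` and at
#' least one equals 1 whenever any error is nonzero. When all errors are
#' zero, all NRSE values are 0 (the documented 0/0 convention). Masked pairs
#' get `NA`.
#'
#' @inheritParams nmad
#' @return vector the length of the input, `NA` at masked positions
#' @export
nrse <- function(predicted, experimental, mask = NULL) {
  keep <- check_pairs(predicted, experimental, mask)
  err <- abs(predicted - experimental)
  mx <- max(err[keep])
  out <- rep(NA_real_, length(predicted))
  out[keep] <- if (mx == 0) 0 else err[keep] / mx
  names(out) <- names(predicted)
  out
}

#' Log-shifted absolute mean difference (the calibration fitness)
#'
#' \deqn{AMD = \left|\frac{\sum_n (\ln(x_n + 2) - \ln(y_n + 2))}{N}\right|}
#' over unmasked pairs. The +2 shift maps `[-1,1]` data into `[1,3]` so the
#' logarithm is finite and nonnegative; the log penalizes larger relative
#' differences. Note the absolute value wraps the MEAN: signed per-node
#' errors can cancel, so AMD can be 0 for unequal data. That pathology is
#' intentional and kept — see [amd_strict()] for the per-datum-absolute
#' variant.
#'
#' @inheritParams nmad
#' @return nonnegative scalar
#' @export
amd <- function(predicted, experimental, mask = NULL) {
  keep <- check_pairs(predicted, experimental, mask)
  abs(mean(log(predicted[keep] + 2) - log(experimental[keep] + 2)))
}

#' Per-datum absolute variant of [amd()]
#'
#' Mean of `|ln(x+2) - ln(y+2)|`; immune to sign cancelation. Not the
#' calibration fitness; provided for users who want a cancelation-free error.
#'
#' @inheritParams nmad
#' @return nonnegative scalar
#' @export
amd_strict <- function(predicted, experimental, mask = NULL) {
  keep <- check_pairs(predicted, experimental, mask)
  mean(abs(log(predicted[keep] + 2) - log(experimental[keep] + 2)))
}

#' Paired t-test between two steady states
#'
#' Two-sided paired t-test across the per-node activation values of two
#' steady states (pairing by node). Degenerate cases follow a documented
#' convention: zero-variance differences with zero mean give `p = 1`
#' (not significant); zero-variance differences with nonzero mean are a
#' deterministic uniform shift and are reported significant with `p = 0`.
#' Both carry `degenerate = TRUE`.
#'
#' @param ss_a,ss_b `steady_state` objects (or named numeric vectors) over
#'   the same node set with at least 2 nodes
#' @param alpha significance level (default 0.05)
#' @return list: `p_value`, `significant`, `mean_difference`, `degenerate`,
#'   `method`
#' @export
steady_state_ttest <- function(ss_a, ss_b, alpha = 0.05) {
  a <- if (inherits(ss_a, "steady_state")) ss_a$x_star else ss_a
  b <- if (inherits(ss_b, "steady_state")) ss_b$x_star else ss_b
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("steady states cover different node sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) stop("steady states have different lengths")
  if (length(a) < 2) stop("need at least 2 nodes for a t-test")
  d <- b - a
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    m <- mean(d)
    warning("degenerate t-test: paired differences have zero variance")
    return(list(p_value = if (m == 0) 1 else 0, significant = m != 0,
                mean_difference = m, degenerate = TRUE,
                method = "paired t-test (two-sided, degenerate)"))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(p_value = tt$p.value, significant = tt$p.value < alpha,
       mean_difference = unname(tt$estimate), degenerate = FALSE,
       method = "paired t-test (two-sided)")
}

#' Sign-permutation test between two steady states
#'
#' Nonparametric alternative to [steady_state_ttest()]: permutes the signs of
#' the paired per-node differences and compares the observed `|mean|` to the
#' permutation distribution.
#'
#' @inheritParams steady_state_ttest
#' @param n_perm number of sign permutations
#' @param seed RNG seed
#' @return list: `p_value`, `significant`, `mean_difference`
#' @export
steady_state_permtest <- function(ss_a, ss_b, alpha = 0.05,
                                  n_perm = 10000, seed = 0) {
  a <- if (inherits(ss_a, "steady_state")) ss_a$x_star else ss_a
  b <- if (inherits(ss_b, "steady_state")) ss_b$x_star else ss_b
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  d <- b - a
  obs <- abs(mean(d))
  perm <- with_preserved_rng({
    set.seed(as.integer(seed))
    vapply(seq_len(n_perm), function(i)
      abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE))), numeric(1))
  })
  p <- (1 + sum(perm >= obs - 1e-15)) / (n_perm + 1)
  list(p_value = p, significant = p < alpha, mean_difference = mean(d))
}

#' A behavior rule for qualitative scoring
#'
#' Encodes a literature-established expectation: under `stimulus`, the
#' `target` node's response should go `up`, `down`, or stay `unchanged`.
#'
#' @param stimulus a `perturbation`
#' @param target node id
#' @param expected one of `"up"`, `"down"`, `"unchanged"`
#' @param citation free-text provenance note
#' @return object of class `behavior_rule`
#' @export
behavior_rule <- function(stimulus, target, expected = c("up", "down", "unchanged"),
                          citation = "") {
  expected <- match.arg(expected)
  stopifnot(inherits(stimulus, "perturbation"), is.character(target))
  structure(list(stimulus = stimulus, target = target, expected = expected,
                 citation = citation), class = "behavior_rule")
}

#' Qualitative behavior score
#'
#' For each rule, simulates the stimulus response and classifies the target's
#' delta as `up` (`> threshold`), `down` (`< -threshold`), else `unchanged`;
#' the score is matched rules over evaluable rules. Rules whose simulation
#' does not converge are marked unevaluable and excluded from the
#' denominator.
#'
#' @param net a `regnet`
#' @param params `node_params`
#' @param rules list of [behavior_rule()] objects (non-empty)
#' @param direction_threshold classification threshold on the response delta
#'   (default 0.1)
#' @param solver a `solver_config`
#' @param seed baseline seed (defaults to the solver's seed)
#' @return list: `score`, `table` (per-rule data.frame), `n_unevaluable`
#' @export
qualitative_score <- function(net, params, rules, direction_threshold = 0.1,
                              solver = solver_config(), seed = solver$seed) {
  if (length(rules) == 0) stop("undefined score: empty rule list")
  bad <- vapply(rules, function(r) !(r$target %in% net$nodes$id), logical(1))
  if (any(bad))
    stop("rule target(s) not in network: ",
         paste(vapply(rules[bad], `[[`, "", "target"), collapse = ", "))
  rows <- lapply(rules, function(r) {
    rv <- tryCatch(response(net, params, r$stimulus, seed, solver),
                   chondronet_nonconverged = function(e) NULL)
    if (is.null(rv))
      return(data.frame(target = r$target, expected = r$expected,
                        observed = NA_character_, delta = NA_real_,
                        matched = NA, evaluable = FALSE))
    d <- unname(rv$delta[r$target])
    obs <- if (d > direction_threshold) "up"
           else if (d < -direction_threshold) "down" else "unchanged"
    data.frame(target = r$target, expected = r$expected, observed = obs,
               delta = d, matched = obs == r$expected, evaluable = TRUE)
  })
  tab <- do.call(rbind, rows)
  ev <- tab$evaluable
  if (!any(ev)) stop("undefined score: no rule could be evaluated")
  list(score = sum(tab$matched[ev]) / sum(ev), table = tab,
       n_unevaluable = sum(!ev))
}

#' Evaluate a network against a perturbation-response dataset
#'
#' Simulates every experiment in the dataset and pools the unmasked
#' (prediction, measurement) pairs to compute NMAD (fraction and percent),
#' per-point NRSE, and AMD; optionally scores qualitative behavior rules.
#'
#' @param net a `regnet`
#' @param params `node_params`
#' @param dataset a `perturbation_dataset`
#' @param rules optional list of behavior rules
#' @param direction_threshold threshold for qualitative classification
#' @param solver a `solver_config`
#' @param seed baseline seed (defaults to the solver's seed)
#' @return object of class `evaluation_report`
#' @export
evaluate_network <- function(net, params, dataset, rules = NULL,
                             direction_threshold = 0.1,
                             solver = solver_config(), seed = solver$seed) {
  stopifnot(inherits(dataset, "perturbation_dataset"))
  sim <- simulate_dataset_predictions(net, params, dataset, seed, solver)
  keep <- !sim$masked
  if (!any(keep)) stop("undefined metrics: all dataset cells masked")
  rep <- list(
    nmad = nmad(sim$predicted[keep], sim$measured[keep]),
    nrse = nrse(sim$predicted, sim$measured, mask = sim$masked),
    amd = amd(sim$predicted[keep], sim$measured[keep]),
    n_pairs = sum(keep),
    n_nonconverged = sim$n_nonconverged,
    pairs = data.frame(experiment = sim$experiment, node = sim$node,
                       predicted = sim$predicted, measured = sim$measured,
                       masked = sim$masked))
  rep$nmad_percent <- 100 * rep$nmad
  if (!is.null(rules) && length(rules) > 0) {
    qs <- qualitative_score(net, params, rules, direction_threshold, solver, seed)
    rep$qualitative_accuracy <- qs$score
    rep$rule_table <- qs$table
  } else {
    rep$qualitative_accuracy <- NA_real_
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation: NMAD %.4f (%.4f%%), AMD %.4f over %d pairs\n",
              x$nmad, x$nmad_percent, x$amd, x$n_pairs))
  if (!is.na(x$qualitative_accuracy))
    cat(sprintf("qualitative accuracy: %.1f%%\n", 100 * x$qualitative_accuracy))
  invisible(x)
}

# Pool (prediction, measurement, mask) cells across a dataset's experiments.
# The baseline is integrated once and shared by all experiments (it does not
# depend on the perturbation); numerically identical to calling response()
# per experiment. Non-converged experiments raise unless absorb = TRUE.
simulate_dataset_predictions <- function(net, params, dataset, seed, solver,
                                         absorb = FALSE) {
  nonconv <- function(msg) {
    cond <- structure(class = c("chondronet_nonconverged", "error", "condition"),
                      list(message = msg, call = sys.call(-1)))
    stop(cond)
  }
  fast <- solver$method == "rk4_fixed"
  sys <- if (fast) compile_system(net, params)
  base <- if (fast) baseline_compiled(sys, seed, solver)
         else baseline(net, params, seed, solver)
  if (!base$converged) {
    if (absorb) return(list(experiment = integer(), node = character(),
                            predicted = numeric(), measured = numeric(),
                            masked = logical(),
                            n_nonconverged = length(dataset$experiments)))
    nonconv("baseline steady state did not converge")
  }
  experiment <- integer(); node <- character()
  predicted <- numeric(); measured <- numeric(); masked <- logical()
  n_bad <- 0L
  for (i in seq_along(dataset$experiments)) {
    ex <- dataset$experiments[[i]]
    ss <- if (fast) steady_state_compiled(sys, ex$perturbation, solver)
          else integrate_to_steady_state(net, params, ex$perturbation, solver)
    if (!ss$converged) {
      if (absorb) { n_bad <- n_bad + 1L; next }
      nonconv(paste0("experiment ", i, " steady state did not converge"))
    }
    delta <- ss$x_star - base$x_star
    nm <- names(ex$measured)
    miss <- setdiff(nm, names(delta))
    if (length(miss) > 0)
      stop("dataset measures node(s) absent from network: ",
           paste(miss, collapse = ", "))
    experiment <- c(experiment, rep(i, length(nm)))
    node <- c(node, nm)
    predicted <- c(predicted, unname(delta[nm]))
    measured <- c(measured, unname(ex$measured))
    masked <- c(masked, nm %in% ex$mask)
  }
  list(experiment = experiment, node = node, predicted = predicted,
       measured = measured, masked = masked, n_nonconverged = n_bad)
}
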