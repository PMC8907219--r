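# Synthetic topology-recovery problems for the calibration tests.
#
# Layered design: a handful of input nodes feeding readout nodes. The
# immutable backbone gives every readout 1-2 regulators; mutable candidate
# edges (input -> readout, <= 2 per readout) are the GA's search space, of
# which a known subset is "true". Training data are single-input clamp
# experiments simulated from the true network with the decay source policy,
# so each candidate edge is exercised only by its own source's experiment
# (its source sits at 0 in every other condition). An identifiability screen
# replaces any candidate whose lone bit flip moves the pooled AMD by less
# than `min_effect`, so every bit is visible in the data.

recovery_solver <- function() solver_config(step = 0.2, tol = 1e-5)

make_recovery_problem <- function(master_seed, n_inputs = 6, n_readouts = 14,
                                  n_cand = 15, n_true = 8, min_effect = 2e-4,
                                  solver = recovery_solver()) {
  set.seed(master_seed)
  inputs <- sprintf("IN%02d", seq_len(n_inputs))
  reads <- sprintf("RD%02d", seq_len(n_readouts))
  nodes <- data.frame(id = c(inputs, reads),
                      role = rep_len(node_roles(), n_inputs + n_readouts),
                      accession = NA_character_)
  bb <- do.call(rbind, lapply(reads, function(r) {
    k <- sample(1:2, 1)
    data.frame(source = sample(inputs, k), target = r,
               sign = sample(c("activation", "inhibition"), k, TRUE,
                             prob = c(0.65, 0.35)),
               weight = 1, provenance = "synthetic", mutable = FALSE)
  }))
  pool <- expand.grid(source = inputs, target = reads, stringsAsFactors = FALSE)
  pool <- pool[!(paste(pool$source, pool$target) %in% paste(bb$source, bb$target)), ]
  pool <- pool[sample.int(nrow(pool)), ]
  pool$sign <- sample(c("activation", "inhibition"), nrow(pool), TRUE,
                      prob = c(0.65, 0.35))
  pool$weight <- sample(c(0.5, 1, 1.5, 2), nrow(pool), TRUE)
  pool$provenance <- "synthetic"; pool$mutable <- TRUE
  true_bits <- integer(n_cand); true_bits[sample.int(n_cand, n_true)] <- 1L

  build <- function(cand) {
    template <- regnet(nodes, rbind(bb, cand))
    truth <- decode(true_bits, template)
    params <- node_params(template, source_policy = "decay")
    bs <- baseline(truth, params, solver$seed, solver)
    exps <- lapply(inputs, function(s) {
      pert <- perturbation(clamps = stats::setNames(1, s))
      ss <- integrate_to_steady_state(truth, params, pert, solver)
      list(perturbation = pert, measured = pmin(pmax(ss$x_star - bs$x_star, -1), 1))
    })
    list(template = template, truth = truth, params = params,
         train = perturbation_dataset(exps), bs = bs)
  }
  taken <- seq_len(n_cand); nxt <- n_cand + 1L
  for (round in 1:30) {
    cand <- pool[taken, ]
    pr <- build(cand)
    eff <- vapply(seq_len(n_cand), function(k) {
      g <- true_bits; g[k] <- 1L - g[k]
      as.numeric(fitness(g, pr$template, pr$params, pr$train, ga_config(), solver))
    }, numeric(1))
    weak <- which(eff < min_effect)
    if (length(weak) == 0) break
    for (k in weak) {
      if (nxt > nrow(pool)) stop("candidate pool exhausted")
      taken[k] <- nxt; nxt <- nxt + 1L
    }
    if (round == 30) stop("could not build identifiable problem")
  }
  # validation: all input pairs, noise-free
  vst <- utils::combn(inputs, 2)
  vexp <- lapply(seq_len(ncol(vst)), function(i) {
    pert <- perturbation(clamps = stats::setNames(c(1, 1), vst[, i]))
    ss <- integrate_to_steady_state(pr$truth, pr$params, pert, solver)
    list(perturbation = pert, measured = pmin(pmax(ss$x_star - pr$bs$x_star, -1), 1))
  })
  c(pr, list(val = perturbation_dataset(vexp), true_bits = true_bits))
}

add_measurement_noise <- function(dataset, sd, seed) {
  set.seed(seed)
  dataset$experiments <- lapply(dataset$experiments, function(e) {
    e$measured <- pmin(pmax(e$measured + stats::rnorm(length(e$measured), sd = sd), -1), 1)
    e
  })
  dataset
}

edge_jaccard <- function(bits_a, bits_b) {
  a <- which(bits_a == 1L); b <- which(bits_b == 1L)
  length(intersect(a, b)) / length(union(a, b))
}
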