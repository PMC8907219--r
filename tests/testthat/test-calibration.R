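fast_solver <- solver_config(step = 0.2, tol = 1e-5)

test_that("decode keeps immutable edges and re-tags kept mutable ones", {
  net <- fixture_chondrocyte_network()
  net$edges$mutable[1:10] <- FALSE
  L <- sum(net$edges$mutable)

  full <- decode(rep(1L, L), net)
  expect_equal(n_edges(full), n_edges(net))
  expect_true(all(full$edges$provenance[full$edges$mutable] == "optimized"))

  none <- decode(rep(0L, L), net)
  expect_equal(n_edges(none), 10)
  expect_true(all(!none$edges$mutable))

  tmpl3 <- regnet(edges = data.frame(source = c("A", "A", "B"),
                                     target = c("B", "C", "C"), sign = "+"))
  kept <- decode(c(1L, 0L, 1L), tmpl3)
  expect_equal(paste(kept$edges$source, kept$edges$target), c("A B", "B C"))

  expect_error(decode(c(1L, 0L), tmpl3), "length")
  expect_error(decode(c(1L, 2L, 0L), tmpl3), "binary")
})

test_that("fitness is zero for self-consistent data and reproduces the AMD pathology", {
  net <- random_small_net(42, n = 8, density = 0.25)
  params <- node_params(net)
  spec <- synthetic_spec(n_nodes = 8, n_experiments = 4, seed = 42)
  ds <- generate_dataset(net, spec, params, fast_solver)
  L <- sum(net$edges$mutable)
  expect_identical(as.numeric(fitness(rep(1L, L), net, params, ds,
                                      ga_config(), fast_solver)), 0)

  # cancelation pathology: swapping the two measured values pairs each
  # log-error with its negative, so fitness is 0 despite the mismatch
  stim <- net$edges$source[1]
  probe <- perturbation_dataset(list(list(
    perturbation = perturbation(clamps = stats::setNames(1, stim)),
    measured = stats::setNames(rep(0, n_nodes(net)), net$nodes$id))),
    auto_mask_self = FALSE)
  pred <- chondronet:::simulate_dataset_predictions(net, params, probe, 0, fast_solver)
  two <- order(abs(pred$predicted), decreasing = TRUE)[1:2]  # distinct responses
  swapped <- perturbation_dataset(list(list(
    perturbation = perturbation(clamps = stats::setNames(1, stim)),
    measured = stats::setNames(pred$predicted[rev(two)], pred$node[two]))),
    auto_mask_self = FALSE)
  f0 <- fitness(rep(1L, L), net, params, swapped, ga_config(), fast_solver)
  expect_false(isTRUE(all.equal(pred$predicted[two], pred$predicted[rev(two)])))
  expect_identical(as.numeric(f0), 0)
})

test_that("fitness on a small problem equals the exhaustive oracle path", {
  net <- random_small_net(42, n = 8, density = 0.25)
  params <- node_params(net)
  spec <- synthetic_spec(n_nodes = 8, n_experiments = 4, seed = 42)
  ds <- generate_dataset(net, spec, params, fast_solver)
  L <- sum(net$edges$mutable)
  fc <- chondronet:::make_fitness_cache(net, params, ds, ga_config(), fast_solver)
  set.seed(8)
  for (i in 1:15) {
    g <- as.integer(stats::runif(L) < 0.5)
    expect_identical(fc$eval(g),
                     as.numeric(fitness(g, net, params, ds, ga_config(), fast_solver)))
  }
})

test_that("run_ga is seed-deterministic with non-increasing trajectories", {
  net <- random_small_net(42, n = 8, density = 0.25)
  params <- node_params(net)
  spec <- synthetic_spec(n_nodes = 8, n_experiments = 4, seed = 42)
  ds <- generate_dataset(net, spec, params, fast_solver)
  cfg <- ga_config(population_size = 12, generations = 10, repeats = 2, seed = 7)
  a <- run_ga(net, params, ds, cfg, fast_solver)
  b <- run_ga(net, params, ds, cfg, fast_solver)
  expect_identical(lapply(a$repeats, `[[`, "best_genome"),
                   lapply(b$repeats, `[[`, "best_genome"))
  expect_identical(a$best_fitness, b$best_fitness)
  for (r in a$repeats)
    expect_true(all(diff(r$trajectory) <= 0))
})

test_that("a 1-mutable-edge problem is solved in every repeat", {
  # A -> B is the truth; the edge is the only mutable one
  net <- regnet(edges = data.frame(source = "A", target = "B", sign = "+"))
  params <- node_params(net, source_policy = "decay")
  ds <- perturbation_dataset(list(list(
    perturbation = perturbation(clamps = c(A = 1)),
    measured = c(B = 1))), auto_mask_self = FALSE)
  cfg <- ga_config(population_size = 4, generations = 3, repeats = 5, seed = 1)
  res <- run_ga(net, params, ds, cfg, fast_solver)
  for (r in res$repeats) {
    expect_identical(r$best_genome, 1L)
    expect_lt(r$best_fitness, 1e-3)
  }
})

test_that("select_final ranks lexicographically and flags catabolic baselines", {
  net <- random_small_net(42, n = 8, density = 0.25)
  params <- node_params(net)
  spec <- synthetic_spec(n_nodes = 8, n_experiments = 4, seed = 42)
  ds <- generate_dataset(net, spec, params, fast_solver)
  L <- sum(net$edges$mutable)
  fake_result <- function(genome, fit) {
    structure(list(repeats = list(list(best_genome = genome, best_fitness = fit,
                                       trajectory = fit))),
              class = "calibration_result")
  }
  r1 <- fake_result(rep(1L, L), 0)            # truth: validation NMAD 0
  g2 <- c(0L, rep(1L, L - 1))
  r2 <- fake_result(g2, 1e-6)
  ranked <- select_final(list(r2, r1), net, params,
                         validation_dataset = ds, solver = fast_solver)
  expect_equal(nrow(ranked), 2)
  expect_equal(ranked$genome[1], paste(rep(1, L), collapse = ""))
  expect_true(ranked$validation_nmad[1] <= ranked$validation_nmad[2])
  expect_equal(ranked$rank, 1:2)
  expect_type(ranked$catabolic_baseline, "logical")

  # single candidate: rank 1 with all criteria reported
  solo <- select_final(r1, net, params, validation_dataset = ds,
                       solver = fast_solver)
  expect_equal(nrow(solo), 1)
  expect_named(solo, c("genome", "qualitative_accuracy", "validation_nmad",
                       "training_amd", "catabolic_baseline", "n_edges", "rank"))
})

test_that("select_final surfaces the fit-vs-plausibility trade-off", {
  # data generated from a catabolic-biased truth: the best-fit candidate has
  # a catabolic baseline, a pruned alternative is anabolic but fits worse
  nodes <- data.frame(id = c("S", "CAT", "ANA"),
                      role = c("other", "pro_inflammatory", "growth_factor"),
                      accession = NA)
  edges <- data.frame(source = c("CAT", "S", "S"),
                      target = c("CAT", "CAT", "ANA"),
                      sign = c("+", "+", "+"),
                      weight = 1, provenance = "synthetic",
                      mutable = c(TRUE, FALSE, FALSE))
  net <- regnet(nodes, edges)
  params <- node_params(net, source_policy = "decay")
  ds <- local({
    pert <- perturbation(clamps = c(S = 1))
    bs <- baseline(net, params, 0, fast_solver)
    ss <- integrate_to_steady_state(net, params, pert, fast_solver)
    perturbation_dataset(list(list(perturbation = pert,
                                   measured = pmin(pmax(ss$x_star - bs$x_star, -1), 1))))
  })
  keep <- structure(list(repeats = list(list(best_genome = 1L, best_fitness = 0,
                                             trajectory = 0))),
                    class = "calibration_result")
  drop <- structure(list(repeats = list(list(best_genome = 0L, best_fitness = 0.05,
                                             trajectory = 0.05))),
                    class = "calibration_result")
  ranked <- select_final(list(keep, drop), net, params,
                         validation_dataset = ds, solver = fast_solver)
  # the self-sustaining catabolic loop is flagged; the pruned network is not
  expect_true(ranked$catabolic_baseline[ranked$genome == "1"])
  expect_false(ranked$catabolic_baseline[ranked$genome == "0"])
  expect_equal(ranked$genome[1], "1")  # better fit still ranks first
})

test_that("non-converging simulations poison fitness with +Inf", {
  # a horizon too short to converge marks the genome non-converged
  net <- chain_net()
  params <- node_params(net)
  ds <- perturbation_dataset(list(list(
    perturbation = perturbation(clamps = c(A = 1)),
    measured = c(B = 1))), auto_mask_self = FALSE)
  cramped <- solver_config(step = 0.01, tol = 1e-9, t_max = 0.1)
  f <- fitness(1L, net, params, ds, ga_config(), cramped)
  expect_identical(as.numeric(f), Inf)
  expect_true(attr(f, "nonconverged"))
  # run_ga absorbs the poisoned genome rather than raising: only the
  # edge-dropped genome (whose nodes are all sources, converging trivially)
  # remains viable and wins despite fitting badly
  res <- run_ga(net, params, ds, ga_config(population_size = 4, generations = 2,
                                           repeats = 1, seed = 1), cramped)
  expect_identical(res$best_genome, 0L)
  expect_true(is.finite(res$best_fitness))
  expect_gt(res$n_nonconverged, 0)
})

test_that("recovery survives measurement noise (robustness regression)", {
  # i.i.d. Gaussian noise (sd 0.1) on the training measurements degrades but
  # does not destroy topology recovery; 10 master seeds, median Jaccard >= 0.5
  solver <- recovery_solver()
  js <- vapply(1:10, function(master_seed) {
    pr <- make_recovery_problem(master_seed)
    noisy <- add_measurement_noise(pr$train, sd = 0.1, seed = master_seed + 999)
    cfg <- ga_config(population_size = 50, generations = 100, repeats = 16,
                     seed = master_seed)
    res <- run_ga(pr$template, pr$params, noisy, cfg, solver)
    ranked <- select_final(res, pr$template, pr$params,
                           validation_dataset = pr$val, solver = solver)
    edge_jaccard(attr(ranked, "genomes")[[1]], pr$true_bits)
  }, numeric(1))
  expect_gte(stats::median(js), 0.5)
})
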