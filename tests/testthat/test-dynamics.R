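test_that("total_input matches the closed-form cases", {
  net <- regnet(edges = data.frame(
    source = c("A", "I1"), target = c("B", "B"), sign = c("+", "-")))

  # single activator at 1 -> saturation to 1; inhibitor inactive at 0
  expect_equal(total_input("B", c(A = 1, I1 = 0), net), 1)
  # single inhibitor at 1 with activator absent
  inh <- regnet(edges = data.frame(source = "I1", target = "B", sign = "-"))
  expect_equal(total_input("B", c(I1 = 1), inh), 0)
  # activator at 0.5: (2/1) * (0.5/1.5) = 2/3
  act <- chain_net()
  expect_equal(total_input("B", c(A = 0.5), act), 2 / 3)
  # both blocks multiply
  expect_equal(total_input("B", c(A = 1, I1 = 1), net), 0)

  expect_error(total_input("A", c(A = 0.5, B = 0), act), "no incoming")
})

test_that("total_input handles weights and saturation identities", {
  # all activators at 1 gives omega = 1 for any positive weights
  for (w in list(c(1, 1), c(0.3, 2.5), c(10, 0.01))) {
    net <- regnet(edges = data.frame(source = c("A", "B"), target = "C",
                                     sign = "+", weight = w))
    expect_equal(total_input("C", c(A = 1, B = 1), net), 1, tolerance = 1e-15)
  }
  # single activator at 1, arbitrary weight: ((1+a)/a) * (a/(1+a)) = 1
  net <- regnet(edges = data.frame(source = "A", target = "B", sign = "+",
                                   weight = 3.7))
  expect_equal(total_input("B", c(A = 1), net), 1)
})

test_that("activation has exact anchors and matches the independent oracle", {
  for (h in c(1, 10, 100)) {
    expect_equal(activation(0, h), 0, tolerance = 1e-12)
    expect_equal(activation(0.5, h), 0.5, tolerance = 1e-12)
    expect_equal(activation(1, h), 1, tolerance = 1e-12)
  }
  # derived value, frozen from 30-digit arithmetic
  expect_equal(activation(2 / 3, 10), 0.845759123659818, tolerance = 1e-12)
  expect_equal(activation(0.25, 10), 0.0701037165451082, tolerance = 1e-12)
  # strictly increasing
  om <- seq(0, 1, by = 0.01)
  expect_true(all(diff(activation(om, 10)) > 0))
  # grid agreement with the helper oracle
  expect_equal(activation(om, 7), phi_oracle(om, 7), tolerance = 1e-14)
  expect_error(activation(1.5), "omega")
})

test_that("omega is monotone in regulator levels", {
  net <- regnet(edges = data.frame(source = c("A", "B", "C"), target = "T",
                                   sign = c("+", "+", "-"),
                                   weight = c(1, 2, 1.5)))
  set.seed(42)
  for (i in 1:50) {
    x <- stats::runif(3)
    st <- c(A = x[1], B = x[2], C = x[3])
    eps <- 1e-6
    base <- total_input("T", st, net)
    up_a <- total_input("T", pmin(st + c(eps, 0, 0), 1), net)
    up_b <- total_input("T", pmin(st + c(0, eps, 0), 1), net)
    up_c <- total_input("T", pmin(st + c(0, 0, eps), 1), net)
    expect_gte(up_a, base)
    expect_gte(up_b, base)
    expect_lte(up_c, base)
  }
})

test_that("rhs matches the sigmoid-minus-decay form at fixed points", {
  net <- chain_net()
  params <- node_params(net)
  # activator clamped at 1, x_B = 1: dx = phi(1) - 1 = 0
  d <- rhs(c(A = 1, B = 1), net, params, clamps = c(A = 1))
  expect_equal(unname(d["B"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["A"]), 0)
  # off fixed point
  d0 <- rhs(c(A = 0, B = 0), net, params, clamps = c(A = 0))
  expect_equal(unname(d0["B"]), 0, tolerance = 1e-12)
  # pure decay at x_B = 0.5 with activator at 0
  dd <- rhs(c(A = 0, B = 0.5), net, params, clamps = c(A = 0))
  expect_equal(unname(dd["B"]), -0.5, tolerance = 1e-12)
})

test_that("chain steady states match scalar fixed-point analysis", {
  net <- chain_net()
  params <- node_params(net)
  ss1 <- integrate_to_steady_state(net, params, perturbation(clamps = c(A = 1)))
  expect_true(ss1$converged)
  expect_equal(unname(ss1$x_star["B"]), 1, tolerance = 1e-5)
  expect_equal(unname(ss1$x_star["A"]), 1)

  ss0 <- integrate_to_steady_state(net, params, perturbation(clamps = c(A = 0)))
  expect_equal(unname(ss0$x_star["B"]), 0, tolerance = 1e-5)

  # A clamped at 0.5: x_B* solves x = phi(2/3); root-finding oracle
  ssh <- integrate_to_steady_state(net, params, perturbation(clamps = c(A = 0.5)))
  root <- stats::uniroot(function(x) phi_oracle(2 / 3, 10) - x, c(0, 1),
                         tol = 1e-12)$root
  expect_equal(unname(ssh$x_star["B"]), root, tolerance = 1e-5)
  expect_equal(unname(ssh$x_star["B"]), 0.845759123659818, tolerance = 1e-5)
})

test_that("clamped nodes equal their clamp value exactly at every report", {
  net <- fixture_chondrocyte_network()
  params <- node_params(net)
  pert <- perturbation(clamps = c(IL1B = 0.37, TGFB = 1, IL4 = 0))
  ss <- integrate_to_steady_state(net, params, pert)
  expect_identical(unname(ss$x_star[c("IL1B", "TGFB", "IL4")]), c(0.37, 1, 0))
})

test_that("perturbation validates its inputs", {
  expect_error(perturbation(initial = c(A = 2)), "\\[0,1\\]")
  expect_error(perturbation(initial = c(A = 0.5), clamps = c(A = 1)), "both")
  expect_error(perturbation(initial = 0.5), "named")
  expect_error(integrate_to_steady_state(chain_net(), node_params(chain_net()),
                                         perturbation(clamps = c(Z = 1))),
               "unknown node")
})

test_that("baseline is seed-deterministic and respects pure decay", {
  net <- fixture_chondrocyte_network()
  params <- node_params(net)
  a <- baseline(net, params, seed = 0)
  b <- baseline(net, params, seed = 0)
  expect_identical(a$x_star, b$x_star)
  expect_true(a$converged)
  c <- baseline(net, params, seed = 1)
  expect_false(identical(a$x_star, c$x_star))

  # pure-decay network: all-zero attractor regardless of seed
  dec <- regnet(edges = data.frame(source = "A", target = "B", sign = "+"))
  pd <- node_params(dec, source_policy = "decay")
  for (seed in 0:2)
    expect_true(all(baseline(dec, pd, seed)$x_star < 1e-4))
})

test_that("toggle switch has two attractors matching the bisection oracle", {
  net <- toggle_net()
  params <- node_params(net)
  up <- integrate_to_steady_state(net, params,
                                  perturbation(initial = c(A = 0.9, B = 0.05)))
  dn <- integrate_to_steady_state(net, params,
                                  perturbation(initial = c(A = 0.05, B = 0.9)))
  expect_true(up$converged && dn$converged)
  expect_false(isTRUE(all.equal(up$x_star, dn$x_star)))
  # (1,0) and (0,1) are exact fixed points of the closed form: the bisection
  # oracle for the frozen-opponent 1-d system must contain the attained state
  fp_hi <- toggle_fixed_points(xi = 0)   # opponent silenced
  expect_true(min(abs(fp_hi - up$x_star["A"])) < 1e-4)
  fp_lo <- toggle_fixed_points(xi = 1)   # opponent saturated
  expect_true(min(abs(fp_lo - up$x_star["B"])) < 1e-4)
  expect_equal(unname(up$x_star), c(1, 0), tolerance = 1e-4)
  expect_equal(unname(dn$x_star), c(0, 1), tolerance = 1e-4)
})

test_that("response subtracts the baseline and stays in [-1,1]", {
  dec <- chain_net()
  pd <- node_params(dec, source_policy = "decay")
  # baseline attractor is all-zero; clamping A at 1 drives B to 1
  rv <- response(dec, pd, perturbation(clamps = c(A = 1)), seed = 0)
  expect_equal(unname(rv$delta["B"]), 1, tolerance = 1e-4)
  expect_true(all(rv$delta >= -1 & rv$delta <= 1))

  # trivial perturbation on a deterministic attractor: delta 0
  net <- fixture_chondrocyte_network()
  params <- node_params(net)
  base <- baseline(net, params, 0)
  same <- response(net, params,
                   perturbation(initial = base$x_star), seed = 0)
  expect_true(max(abs(same$delta)) < 1e-4)
})

test_that("inhibition response reaches -1 on the self-sustaining target", {
  # A -| B, B self-activating: from a high-B initial state the baseline-free
  # fixed point is B = 1; clamping A at 1 collapses B to 0
  net <- regnet(edges = data.frame(source = c("A", "B"), target = c("B", "B"),
                                   sign = c("-", "+")))
  params <- node_params(net, source_policy = "decay")
  hi <- integrate_to_steady_state(net, params, perturbation(initial = c(B = 0.9)))
  expect_equal(unname(hi$x_star["B"]), 1, tolerance = 1e-4)
  lo <- integrate_to_steady_state(net, params,
                                  perturbation(initial = c(B = 0.9), clamps = c(A = 1)))
  expect_equal(unname(lo$x_star["B"]), 0, tolerance = 1e-4)
  expect_equal(unname(lo$x_star["B"] - hi$x_star["B"]), -1, tolerance = 1e-3)
})

test_that("states remain bounded for random networks and perturbations", {
  set.seed(7)
  for (i in 1:40) {
    net <- random_small_net(i + 3000, n = 6 + i %% 5, density = 0.3)
    params <- node_params(net)
    ids <- net$nodes$id
    cl <- sample(ids, sample(0:2, 1))
    pert <- perturbation(
      initial = stats::setNames(stats::runif(2), sample(setdiff(ids, cl), 2)),
      clamps = if (length(cl)) stats::setNames(stats::runif(length(cl)), cl))
    ss <- integrate_to_steady_state(net, params, pert)
    expect_true(all(ss$x_star >= 0 & ss$x_star <= 1))
    if (ss$converged)
      expect_lte(ss$residual, 1e-6)
  }
})

test_that("fixed-step and adaptive solvers agree on the fixture", {
  net <- fixture_chondrocyte_network()
  params <- node_params(net)
  set.seed(11)
  for (i in 1:5) {
    nodes <- sample(net$nodes$id, 2)
    pert <- perturbation(clamps = stats::setNames(round(stats::runif(2), 2), nodes))
    a <- integrate_to_steady_state(net, params, pert, solver_config())
    b <- integrate_to_steady_state(net, params, pert, solver_config(method = "adaptive"))
    expect_true(a$converged && b$converged)
    expect_lt(max(abs(a$x_star - b$x_star)), 1e-6)
  }
})

test_that("non-convergence is reported, not raised", {
  # frustrated negative loop with high gain oscillates
  osc <- regnet(edges = data.frame(source = c("A", "B", "C"),
                                   target = c("B", "C", "A"), sign = "-"))
  params <- node_params(osc, h = 100)
  ss <- integrate_to_steady_state(osc, params,
                                  perturbation(initial = c(A = 1, B = 0, C = 0.5)),
                                  solver_config(t_max = 20))
  expect_false(ss$converged)
  expect_gt(ss$residual, 1e-6)
  expect_error(response(osc, params, perturbation(clamps = c(A = 1)),
                        solver = solver_config(t_max = 20)),
               class = "chondronet_nonconverged")
})

test_that("state CSV export records solver config", {
  net <- chain_net()
  ss <- integrate_to_steady_state(net, node_params(net),
                                  perturbation(clamps = c(A = 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(ss, f, seed = 0)
  lines <- readLines(f)
  expect_match(lines[1], "method=rk4_fixed")
  expect_equal(lines[2], "node,value")
  expect_length(lines, 4)
})
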