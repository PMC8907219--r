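#' Specification for the synthetic-data harness
#'
#' Describes a random ground-truth network and a perturbation-response
#' dataset with the structure of multiplexed cytokine-release experiments:
#' single (or occasionally paired) node stimulations clamped at 1, per-node
#' responses normalized to `[-1,1]`, additive Gaussian measurement noise, and
#' self-readout masking.
#'
#' @param n_nodes number of nodes (>= 2)
#' @param edge_density fraction of ordered node pairs carrying an edge,
#'   in `(0, 1]`
#' @param activation_fraction probability an edge is activating
#' @param n_experiments number of stimulation experiments (>= 1)
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0)
#' @param mask_self_readouts mask the stimulated nodes' own readouts
#'   (default TRUE)
#' @param pair_fraction fraction of experiments using two simultaneous
#'   stimuli (default 0.2)
#' @param seed RNG seed
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_nodes, edge_density = 0.15,
                           activation_fraction = 0.7, n_experiments = 10,
                           noise_sd = 0, mask_self_readouts = TRUE,
                           pair_fraction = 0.2, seed = 0) {
  stopifnot(n_nodes >= 2, edge_density > 0, edge_density <= 1,
            activation_fraction >= 0, activation_fraction <= 1,
            n_experiments >= 1, noise_sd >= 0,
            pair_fraction >= 0, pair_fraction <= 1)
  structure(list(n_nodes = as.integer(n_nodes), edge_density = edge_density,
                 activation_fraction = activation_fraction,
                 n_experiments = as.integer(n_experiments),
                 noise_sd = noise_sd, mask_self_readouts = mask_self_readouts,
                 pair_fraction = pair_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random ground-truth network
#'
#' Draws a signed directed graph over `N<i>` nodes: each ordered non-self
#' pair carries an edge with probability `edge_density` (signs i.i.d.
#' activating with probability `activation_fraction`, weights 1, provenance
#' `"synthetic"`, all mutable). A set of input nodes is designated and extra
#' edges are added until every node is reachable from an input, so the graph
#' has no stranded components. Roles are assigned round-robin from the role
#' vocabulary. Deterministic per seed.
#'
#' @param spec a `synthetic_spec`
#' @return a `regnet` that passes [validate_network()] with zero errors
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_preserved_rng({
    set.seed(spec$seed, kind = "Mersenne-Twister")
    n <- spec$n_nodes
    ids <- sprintf("N%02d", seq_len(n))
    pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
    pairs <- pairs[pairs$source != pairs$target, ]
    take <- stats::runif(nrow(pairs)) < spec$edge_density
    src <- pairs$source[take]; tgt <- pairs$target[take]

    # inputs: prefer nodes with no incoming edges; always at least one
    inputs <- setdiff(seq_len(n), unique(tgt))
    if (length(inputs) == 0) inputs <- sample.int(n, 1)

    # connect stranded nodes: add an edge from a reachable node
    reach <- function(src, tgt) {
      seen <- rep(FALSE, n); seen[inputs] <- TRUE
      frontier <- inputs
      while (length(frontier) > 0) {
        nxt <- unique(tgt[src %in% frontier & !seen[tgt]])
        nxt <- nxt[!seen[nxt]]
        seen[nxt] <- TRUE
        frontier <- nxt
      }
      seen
    }
    for (tries in 1:(2 * n)) {
      seen <- reach(src, tgt)
      if (all(seen)) break
      orphan <- which(!seen)[1]
      from <- sample(which(seen), 1)
      src <- c(src, from); tgt <- c(tgt, orphan)
    }
    if (!all(reach(src, tgt))) stop("density too low to connect network")

    sign <- ifelse(stats::runif(length(src)) < spec$activation_fraction,
                   "activation", "inhibition")
    nodes <- data.frame(id = ids,
                        role = rep_len(node_roles(), n),
                        accession = NA_character_, stringsAsFactors = FALSE)
    edges <- unique(data.frame(source = ids[src], target = ids[tgt], sign = sign,
                               weight = 1, provenance = "synthetic", mutable = TRUE,
                               stringsAsFactors = FALSE))
    regnet(nodes = nodes, edges = edges)
  })
}

#' Generate a perturbation-response dataset from a network
#'
#' For each experiment, one stimulus node (or two, with probability
#' `pair_fraction`) is drawn from the nodes with outgoing edges and clamped
#' at 1; the true response (perturbed steady state minus the seeded random
#' baseline) is computed with the dynamics engine, i.i.d. Gaussian noise of
#' sd `noise_sd` is added, values are clipped to `[-1,1]`, and — if
#' `mask_self_readouts` — the stimulated nodes' own readouts are masked.
#' Experiments whose simulation fails to converge are regenerated with a
#' different stimulus (counted in the `n_regenerated` attribute).
#' Deterministic per `spec$seed`.
#'
#' @param net a `regnet`
#' @param spec a `synthetic_spec`
#' @param params optional `node_params` (default: unit weights, h = 10,
#'   gamma = 1)
#' @param solver a `solver_config`
#' @return a `perturbation_dataset` with attributes `truth` (noise-free
#'   deltas per experiment) and `n_regenerated`
#' @export
generate_dataset <- function(net, spec, params = node_params(net),
                             solver = solver_config()) {
  stopifnot(inherits(net, "regnet"), inherits(spec, "synthetic_spec"))
  # baseline seed follows the solver convention (same stream the evaluation
  # and calibration layers use), so noise-free datasets are exactly
  # self-consistent with fitness()
  base <- baseline(net, params, solver$seed, solver)
  if (!base$converged) stop("baseline did not converge")
  candidates <- unique(net$edges$source)
  if (length(candidates) == 0) stop("network has no regulating nodes to stimulate")
  with_preserved_rng({
    set.seed(spec$seed + 1L, kind = "Mersenne-Twister")
    experiments <- vector("list", spec$n_experiments)
    truth <- vector("list", spec$n_experiments)
    n_regen <- 0L
    for (i in seq_len(spec$n_experiments)) {
      for (attempt in 1:20) {
        k <- if (length(candidates) > 1 && stats::runif(1) < spec$pair_fraction) 2 else 1
        stim <- sample(candidates, k)
        pert <- perturbation(clamps = stats::setNames(rep(1, k), stim))
        ss <- integrate_to_steady_state(net, params, pert, solver)
        if (ss$converged) break
        n_regen <- n_regen + 1L
        if (attempt == 20) stop("could not find a converging stimulus for experiment ", i)
      }
      delta <- ss$x_star - base$x_star
      # standard normals scaled afterwards, so the RNG stream (and hence the
      # stimulus sequence) is identical across noise levels
      noisy <- delta + spec$noise_sd * stats::rnorm(length(delta))
      noisy <- pmin(pmax(noisy, -1), 1)
      experiments[[i]] <- list(
        perturbation = pert,
        measured = noisy,
        mask = if (spec$mask_self_readouts) stim else character())
      truth[[i]] <- delta
    }
    ds <- perturbation_dataset(experiments, auto_mask_self = spec$mask_self_readouts)
    attr(ds, "truth") <- truth
    attr(ds, "n_regenerated") <- n_regen
    ds
  })
}

#' The packaged illustrative chondrocyte network
#'
#' A 28-node signed network over the chondrocyte secretome vocabulary
#' (proinflammatory cytokines, anti-inflammatory interleukins, growth
#' factors, matrix metalloproteinases and aggrecanases, structural proteins,
#' pain- and apoptosis-related factors, NO/ROS radicals), with
#' literature-motivated example edges such as IL1B activating MMP13, TNF-α
#' inhibiting TGF-β, and IL-4 activating IL-10 and IL-13. UniProt accessions
#' are attached where the molecule maps to a single human protein.
#'
#' This fixture is ILLUSTRATIVE: it covers the node vocabulary and the kind
#' of connectivity reported for chondrocyte regulation, but it is NOT a
#' published, curated topology and carries no claim of biological fidelity.
#' It exists so that examples, tests and the command-line workflow run
#' without external downloads.
#'
#' @return a `regnet` (edges provenance `"literature"`, all mutable)
#' @export
fixture_chondrocyte_network <- function() {
  nodes <- data.frame(
    id = c("IL1B", "TNFA", "IL6", "IL8", "IL17", "IL18", "LIF", "IFNG",
           "IL4", "IL10", "IL13",
           "TGFB", "FGF2", "BMP2", "IGF1",
           "MMP1", "MMP3", "MMP13", "ADAMTS",
           "TIMP", "COL2A", "ACAN",
           "VEGF", "PGE2", "NO", "ROS", "CYCS", "CASP8"),
    role = c(rep("pro_inflammatory", 8),
             rep("anti_inflammatory", 3),
             rep("growth_factor", 4),
             rep("degrading_enzyme", 4),
             "other", "structural_protein", "structural_protein",
             "pain_related", "pain_related", "other", "other",
             "apoptosis_related", "apoptosis_related"),
    accession = c("P01584", "P01375", "P05231", "P10145", "Q16552", "Q14116",
                  NA, NA,
                  "P05112", "P22301", "P35225",
                  "P01137", "P09038", "P12643", "P05019",
                  "P03956", "P08254", "P45452", "O75173",
                  "P01033", "P02458", "P16112",
                  "P15692", NA, NA, NA, "P99999", "Q14790"),
    stringsAsFactors = FALSE)

  E <- function(s, sg, t) data.frame(source = s, sign = sg, target = t,
                                     stringsAsFactors = FALSE)
  edges <- rbind(
    E("IL1B", "+", c("MMP1", "MMP3", "MMP13", "ADAMTS", "IL6", "IL8", "NO", "PGE2")),
    E("IL1B", "-", c("COL2A", "ACAN", "TGFB")),
    E("TNFA", "+", c("MMP1", "MMP3", "MMP13", "IL6", "NO")),
    E("TNFA", "-", c("TGFB", "COL2A")),
    E("IL6",  "+", c("MMP13", "VEGF")),
    E("IL8",  "+", "MMP3"),
    E("IL17", "+", c("IL6", "MMP3")),
    E("IL18", "+", c("IL6", "MMP13")),
    E("LIF",  "+", c("MMP1", "IL6")),
    E("IFNG", "+", "NO"),
    E("NO",   "+", c("IL18", "CYCS", "CASP8", "MMP13")),
    E("ROS",  "+", c("NO", "CASP8")),
    E("CYCS", "+", "CASP8"),
    E("TGFB", "+", c("COL2A", "ACAN", "TIMP")),
    E("TGFB", "-", "MMP13"),
    E("IGF1", "+", c("COL2A", "ACAN")),
    E("BMP2", "+", c("COL2A", "ACAN")),
    E("FGF2", "+", "MMP13"),
    E("FGF2", "-", "ACAN"),
    E("IL4",  "+", c("IL10", "IL13")),
    E("IL4",  "-", c("TNFA", "MMP3")),
    E("IL10", "-", c("IL1B", "TNFA", "IL6")),
    E("IL13", "-", c("MMP3", "IL1B")),
    E("TIMP", "-", c("MMP1", "MMP3", "MMP13")),
    E("ADAMTS", "-", "ACAN"),
    E("MMP13", "-", "COL2A"),
    E("MMP1",  "-", "COL2A"),
    E("PGE2",  "+", c("VEGF", "IL6")))
  edges$weight <- 1
  edges$provenance <- "literature"
  edges$mutable <- TRUE
  regnet(nodes = nodes, edges = edges)
}

#' Write a full synthetic problem to disk
#'
#' Generates a ground-truth network plus training and test datasets and
#' writes `net.tsv` (tsv_extended), `train.csv`, `test.csv` and `truth.json`
#' (ground-truth edge list and generator parameters) under `out_dir`.
#'
#' @param spec a `synthetic_spec`
#' @param out_dir output directory
#' @return invisible list of the generated objects
#' @export
generate_problem_files <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(spec)
  params <- node_params(net)
  train <- generate_dataset(net, spec, params)
  test_spec <- spec
  test_spec$seed <- spec$seed + 1000L
  test <- generate_dataset(net, test_spec, params)
  write_network(net, file.path(out_dir, "net.tsv"), "tsv_extended")
  write_dataset(train, file.path(out_dir, "train.csv"))
  write_dataset(test, file.path(out_dir, "test.csv"))
  jsonlite::write_json(
    list(edges = net$edges[, c("source", "sign", "target")],
         noise_sd = spec$noise_sd, seed = spec$seed,
         n_nodes = spec$n_nodes, n_experiments = spec$n_experiments),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(network = net, train = train, test = test))
}
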