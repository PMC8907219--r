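#' Genetic-algorithm configuration
#'
#' Topology calibration searches over binary edge-inclusion genomes (edge
#' deletion only; no additions, no sign flips). Defaults: population 50,
#' 100 generations, uniform crossover at rate 0.8, per-bit mutation at
#' `1/genome length` (set `mutation_rate = NA` for that adaptive default),
#' tournament selection of size 3, elitism 2, 100 independent repeats.
#'
#' @param population_size integer >= 2
#' @param generations integer >= 1
#' @param crossover_rate probability a selected pair is recombined
#' @param mutation_rate per-bit flip probability; `NA` means `1/length(genome)`
#' @param elitism number of best individuals copied unchanged each generation
#' @param tournament_size selection tournament size
#' @param seed master seed; per-repeat seeds are derived from it
#' @param repeats number of independent GA restarts (default 100)
#' @param fitness `"amd"` or `"amd_with_baseline_penalty"`
#' @param penalty_weight weight of the catabolic-baseline penalty (>= 0)
#' @return object of class `ga_config`
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      crossover_rate = 0.8, mutation_rate = NA,
                      elitism = 2, tournament_size = 3, seed = 0,
                      repeats = 100,
                      fitness = c("amd", "amd_with_baseline_penalty"),
                      penalty_weight = 1) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= 2, generations >= 1, repeats >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            is.na(mutation_rate) || (mutation_rate >= 0 && mutation_rate <= 1),
            elitism >= 0, elitism < population_size, penalty_weight >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed), repeats = as.integer(repeats),
                 fitness = fitness, penalty_weight = penalty_weight),
            class = "ga_config")
}

#' Decode a genome into a network
#'
#' Keeps every immutable edge of the template plus the mutable edges whose
#' bit is 1; retained mutable edges are re-tagged provenance `"optimized"`.
#' Genome order follows the row order of mutable edges in
#' `template$edges`.
#'
#' @param genome 0/1 (or logical) vector over the template's mutable edges
#' @param template a `regnet`
#' @return a `regnet`
#' @export
decode <- function(genome, template) {
  stopifnot(inherits(template, "regnet"))
  mut <- which(template$edges$mutable)
  genome <- as.integer(genome)
  if (length(genome) != length(mut))
    stop("genome length ", length(genome), " != mutable edge count ", length(mut))
  if (!all(genome %in% c(0L, 1L))) stop("genome must be binary")
  keep <- sort(c(setdiff(seq_len(nrow(template$edges)), mut), mut[genome == 1L]))
  e <- template$edges[keep, , drop = FALSE]
  e$provenance[e$mutable] <- "optimized"
  regnet(nodes = template$nodes, edges = e)
}

#' GA fitness of a genome
#'
#' Decodes the genome, simulates every experiment in the dataset, and returns
#' the log-shifted AMD over all unmasked (prediction, measurement) pairs
#' pooled across experiments. With `fitness = "amd_with_baseline_penalty"`,
#' adds `penalty_weight` times the mean baseline activation of
#' pro-inflammatory and degrading-enzyme nodes — penalizing topologies whose
#' unstimulated phenotype is already catabolic. Any non-converged simulation
#' poisons the genome: fitness `+Inf` (counted via the `nonconverged`
#' attribute).
#'
#' @param genome binary vector over mutable edges
#' @param template a `regnet`
#' @param params `node_params`
#' @param dataset a `perturbation_dataset`
#' @param config a `ga_config`
#' @param solver a `solver_config`
#' @return nonnegative scalar (possibly `Inf`)
#' @export
fitness <- function(genome, template, params, dataset, config = ga_config(),
                    solver = solver_config()) {
  net <- decode(genome, template)
  sim <- tryCatch(
    simulate_dataset_predictions(net, params, dataset, solver$seed, solver),
    chondronet_nonconverged = function(e) NULL)
  if (is.null(sim)) return(structure(Inf, nonconverged = TRUE))
  keep <- !sim$masked
  if (!any(keep)) stop("undefined fitness: all dataset cells masked")
  f <- amd(sim$predicted[keep], sim$measured[keep])
  if (config$fitness == "amd_with_baseline_penalty") {
    bs <- baseline(net, params, solver$seed, solver)
    if (!bs$converged) return(structure(Inf, nonconverged = TRUE))
    catab <- net$nodes$id[net$nodes$role %in% c("pro_inflammatory", "degrading_enzyme")]
    if (length(catab) > 0)
      f <- f + config$penalty_weight * mean(bs$x_star[catab])
  }
  f
}

# Memoised fitness evaluator shared across repeats of one run_ga call.
# For the fixed-step solver it precompiles the template's weight matrices and
# adds/removes each mutable edge's single matrix cell per genome, which is
# numerically identical to fitness() (every cell holds at most one edge, so
# no floating-point accumulation order is involved); the adaptive solver
# falls back to the public fitness() path.
make_fitness_cache <- function(template, params, dataset, config, solver) {
  cache <- new.env(parent = emptyenv())
  n_bad <- 0L
  fast <- solver$method == "rk4_fixed"
  if (fast) {
    ids <- template$nodes$id
    n <- length(ids)
    e <- template$edges
    mut <- which(e$mutable)
    imm <- regnet(template$nodes, e[!e$mutable, , drop = FALSE])
    sys0 <- compile_system(imm, params)
    mrow <- match(e$target[mut], ids); mcol <- match(e$source[mut], ids)
    mw <- e$weight[mut]; mact <- e$sign[mut] == "activation"
    catab <- which(template$nodes$role %in% c("pro_inflammatory", "degrading_enzyme"))
    penalize <- config$fitness == "amd_with_baseline_penalty"
    eval_raw <- function(genome) {
      sys <- sys0
      keep <- genome == 1L
      ka <- keep & mact; ki <- keep & !mact
      sys$wact[cbind(mrow[ka], mcol[ka])] <- mw[ka]
      sys$winh[cbind(mrow[ki], mcol[ki])] <- mw[ki]
      sys$kind0 <- ifelse(rowSums(sys$wact) + rowSums(sys$winh) == 0, 2L, 0L)
      base <- baseline_compiled(sys, solver$seed, solver)
      if (!base$converged) return(structure(Inf, nonconverged = TRUE))
      predicted <- numeric(); measured <- numeric(); masked <- logical()
      for (ex in dataset$experiments) {
        ss <- steady_state_compiled(sys, ex$perturbation, solver)
        if (!ss$converged) return(structure(Inf, nonconverged = TRUE))
        nm <- names(ex$measured)
        delta <- ss$x_star - base$x_star
        predicted <- c(predicted, unname(delta[nm]))
        measured <- c(measured, unname(ex$measured))
        masked <- c(masked, nm %in% ex$mask)
      }
      f <- amd(predicted[!masked], measured[!masked])
      if (penalize && length(catab) > 0)
        f <- f + config$penalty_weight * mean(base$x_star[catab])
      f
    }
  } else {
    eval_raw <- function(genome) fitness(genome, template, params, dataset,
                                         config, solver)
  }
  list(
    eval = function(genome) {
      key <- paste(genome, collapse = "")
      if (!is.null(cache[[key]])) return(cache[[key]])
      f <- eval_raw(genome)
      if (isTRUE(attr(f, "nonconverged"))) n_bad <<- n_bad + 1L
      cache[[key]] <- as.numeric(f)
      as.numeric(f)
    },
    n_nonconverged = function() n_bad,
    n_evaluated = function() length(ls(cache)))
}

#' Run the genetic-algorithm topology calibration
#'
#' Standard generational GA over binary edge-inclusion genomes: tournament
#' selection, uniform crossover, bit-flip mutation, elitism. `config$repeats`
#' independent restarts are run, each from a seed derived deterministically
#' from `config$seed`; the whole procedure is reproducible bit-for-bit for a
#' fixed master seed. Fitness values are memoised across repeats (the
#' mapping genome -> fitness is deterministic).
#'
#' @inheritParams fitness
#' @return object of class `calibration_result`: per-repeat `best_genome`,
#'   `best_fitness`, `trajectory` (best-so-far per generation,
#'   non-increasing), plus the decoded best network over all repeats
#' @export
run_ga <- function(template, params, dataset, config = ga_config(),
                   solver = solver_config()) {
  stopifnot(inherits(config, "ga_config"))
  L <- sum(template$edges$mutable)
  if (L == 0) stop("template has no mutable edges")
  pmut <- if (is.na(config$mutation_rate)) 1 / L else config$mutation_rate
  fc <- make_fitness_cache(template, params, dataset, config, solver)

  repeat_seeds <- with_preserved_rng({
    set.seed(config$seed, kind = "Mersenne-Twister")
    sample.int(.Machine$integer.max, config$repeats)
  })

  repeats <- lapply(seq_len(config$repeats), function(r) {
    with_preserved_rng({
      set.seed(repeat_seeds[r], kind = "Mersenne-Twister")
      ga_single(L, fc$eval, config, pmut)
    })
  })
  best_r <- which.min(vapply(repeats, `[[`, numeric(1), "best_fitness"))
  structure(list(repeats = repeats,
                 best_genome = repeats[[best_r]]$best_genome,
                 best_fitness = repeats[[best_r]]$best_fitness,
                 best_network = decode(repeats[[best_r]]$best_genome, template),
                 n_nonconverged = fc$n_nonconverged(),
                 n_fitness_evaluations = fc$n_evaluated(),
                 config = config),
            class = "calibration_result")
}

ga_single <- function(L, eval_fn, config, pmut) {
  np <- config$population_size
  pop <- matrix(stats::runif(np * L) < 0.5, nrow = np) * 1L
  fit <- apply(pop, 1, eval_fn)
  best_i <- which.min(fit)
  best_genome <- pop[best_i, ]; best_fit <- fit[best_i]
  trajectory <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    # tournament selection of parents
    select <- function() {
      cand <- sample.int(np, config$tournament_size, replace = TRUE)
      cand[which.min(fit[cand])]
    }
    children <- matrix(0L, nrow = np - config$elitism, ncol = L)
    i <- 1
    while (i <= nrow(children)) {
      p1 <- pop[select(), ]; p2 <- pop[select(), ]
      if (stats::runif(1) < config$crossover_rate) {
        m <- stats::runif(L) < 0.5
        c1 <- ifelse(m, p1, p2); c2 <- ifelse(m, p2, p1)
      } else { c1 <- p1; c2 <- p2 }
      for (ch in list(c1, c2)) {
        if (i > nrow(children)) break
        flip <- stats::runif(L) < pmut
        children[i, ] <- as.integer(xor(ch == 1L, flip))
        i <- i + 1
      }
    }
    pop <- rbind(elite, children)
    fit <- apply(pop, 1, eval_fn)
    gi <- which.min(fit)
    if (fit[gi] < best_fit) { best_fit <- fit[gi]; best_genome <- pop[gi, ] }
    trajectory[g] <- best_fit
  }
  list(best_genome = as.integer(best_genome), best_fitness = best_fit,
       trajectory = trajectory)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: %d repeat(s), best fitness %.6g, %d distinct genomes evaluated\n",
              length(x$repeats), x$best_fitness, x$n_fitness_evaluations))
  invisible(x)
}

#' Exhaustive fitness enumeration (oracle for small problems)
#'
#' Evaluates every genome in the `2^L` search space. Only sensible for
#' `L <= ~14`; used to certify GA optima.
#'
#' @inheritParams fitness
#' @return list: `best_genome`, `best_fitness`, `fitness` (vector of length
#'   `2^L` in lexicographic bit order, bit 1 = least significant)
#' @export
exhaustive_search <- function(template, params, dataset, config = ga_config(),
                              solver = solver_config()) {
  L <- sum(template$edges$mutable)
  if (L > 16) stop("search space too large for exhaustive enumeration")
  fc <- make_fitness_cache(template, params, dataset, config, solver)
  fits <- vapply(seq_len(2^L) - 1, function(k) {
    fc$eval(as.integer(bitwAnd(bitwShiftR(k, 0:(L - 1)), 1L)))
  }, numeric(1))
  k <- which.min(fits) - 1
  list(best_genome = as.integer(bitwAnd(bitwShiftR(k, 0:(L - 1)), 1L)),
       best_fitness = fits[k + 1], fitness = fits)
}

#' Rank calibrated candidate networks for final-model selection
#'
#' The per-repeat GA winners are deduplicated and each candidate is scored
#' on: training AMD (its fitness), validation NMAD against an independent
#' dataset, qualitative behavior accuracy, and whether the unstimulated
#' baseline is catabolic (mean activation of pro-inflammatory and
#' degrading-enzyme nodes exceeds that of growth-factor, anti-inflammatory
#' and structural nodes). Candidates are ranked lexicographically:
#' qualitative accuracy (desc), then validation NMAD (asc), then training
#' AMD (asc). The lexicographic rule is this package's concretization of
#' "careful examination of qualitative and quantitative results"; the
#' catabolic-baseline flag is surfaced, not used for ranking.
#'
#' @param results a `calibration_result` (or list of them)
#' @param template the template `regnet` the genomes index into
#' @param params `node_params`
#' @param behavior_rules optional list of [behavior_rule()]s; NULL leaves
#'   qualitative accuracy `NA` (ties broken by the quantitative criteria)
#' @param validation_dataset optional independent `perturbation_dataset`
#' @param solver a `solver_config`
#' @return data.frame ranked best-first, with a `genomes` attribute (list of
#'   candidate genomes in ranked order)
#' @export
select_final <- function(results, template, params, behavior_rules = NULL,
                         validation_dataset = NULL, solver = solver_config()) {
  if (inherits(results, "calibration_result")) results <- list(results)
  reps <- unlist(lapply(results, `[[`, "repeats"), recursive = FALSE)
  stopifnot(length(reps) >= 1)
  keys <- vapply(reps, function(r) paste(r$best_genome, collapse = ""), character(1))
  uniq <- !duplicated(keys)
  genomes <- lapply(reps[uniq], `[[`, "best_genome")
  train_amd <- vapply(reps[uniq], `[[`, numeric(1), "best_fitness")

  rows <- lapply(seq_along(genomes), function(i) {
    net <- decode(genomes[[i]], template)
    val_nmad <- NA_real_
    if (!is.null(validation_dataset)) {
      sim <- tryCatch(simulate_dataset_predictions(net, params, validation_dataset,
                                                   solver$seed, solver),
                      chondronet_nonconverged = function(e) NULL)
      if (!is.null(sim) && any(!sim$masked))
        val_nmad <- nmad(sim$predicted[!sim$masked], sim$measured[!sim$masked])
    }
    qual <- NA_real_
    if (!is.null(behavior_rules) && length(behavior_rules) > 0)
      qual <- tryCatch(
        qualitative_score(net, params, behavior_rules, seed = solver$seed,
                          solver = solver)$score,
        error = function(e) NA_real_)
    bs <- baseline(net, params, solver$seed, solver)
    catab_ids <- net$nodes$id[net$nodes$role %in% c("pro_inflammatory", "degrading_enzyme")]
    anab_ids <- net$nodes$id[net$nodes$role %in%
                               c("anti_inflammatory", "growth_factor", "structural_protein")]
    catabolic <- length(catab_ids) > 0 && length(anab_ids) > 0 &&
      mean(bs$x_star[catab_ids]) > mean(bs$x_star[anab_ids])
    data.frame(genome = paste(genomes[[i]], collapse = ""),
               qualitative_accuracy = qual, validation_nmad = val_nmad,
               training_amd = train_amd[i], catabolic_baseline = catabolic,
               n_edges = n_edges(net))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(tab$qualitative_accuracy), -Inf, tab$qualitative_accuracy),
               ifelse(is.na(tab$validation_nmad), Inf, tab$validation_nmad),
               tab$training_amd)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "genomes") <- genomes[ord]
  tab
}
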