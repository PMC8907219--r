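OA_CYTOKINES <- c("IL1B", "TNFA", "IL6", "IL8", "IL17", "IL18")
ACS_NODES <- c("TGFB", "IGF1", "IL4", "IL10")

#' Nodes used by the canned osteoarthritis scenarios
#'
#' `oa_cytokines()`: the six proinflammatory induction cytokines.
#' `acs_nodes()`: the anabolic components of autologous conditioned serum
#' (ACS); the serum's IL-1 receptor antagonist is modeled separately as an
#' `IL1B` clamp at 0.
#'
#' @return character vector of canonical node ids
#' @export
oa_cytokines <- function() OA_CYTOKINES

#' @rdname oa_cytokines
#' @export
acs_nodes <- function() ACS_NODES

require_nodes <- function(net, ids) {
  missing <- setdiff(ids, net$nodes$id)
  if (length(missing) > 0)
    stop("network lacks required node(s): ", paste(missing, collapse = ", "))
}

#' Osteoarthritis induction steady state
#'
#' Clamps the six proinflammatory cytokines (IL-1\eqn{\beta}, TNF-\eqn{\alpha},
#' IL-6, IL-8, IL-17, IL-18) at 1 and integrates to the "OA-like" catabolic
#' steady state.
#'
#' @param net a `regnet` containing all six cytokine nodes
#' @param params `node_params`
#' @param solver a `solver_config`
#' @return a `steady_state`
#' @export
oa_induction <- function(net, params, solver = solver_config()) {
  require_nodes(net, OA_CYTOKINES)
  pert <- perturbation(clamps = stats::setNames(rep(1, 6), OA_CYTOKINES))
  integrate_to_steady_state(net, params, pert, solver)
}

#' Autologous conditioned serum (ACS) treatment scenarios
#'
#' Simulates intra-articular ACS on an OA-induced joint. In every scenario
#' the ACS anabolic nodes (TGFB, IGF1, IL4, IL10) are clamped at 1 and IL1B
#' is clamped at 0 (the serum's IL-1 receptor antagonist blocks IL-1\eqn{\beta}
#' signaling). The three scenarios differ in the assumed persistence of
#' synovitis, expressed through the five remaining proinflammatory cytokines
#' (TNFA, IL6, IL8, IL17, IL18):
#' \describe{
#'   \item{1}{left free — ACS fully silences the synovium;}
#'   \item{2}{clamped at 1 — sustained synovitis keeps catabolic signaling
#'     at maximum;}
#'   \item{3}{clamped at 0.5 — ACS partially mitigates synovial
#'     inflammation.}
#' }
#' Treatment integration starts from the OA-like steady state (the joint is
#' diseased when treated); a paired t-test gates whether the treated steady
#' state differs significantly from the OA state.
#'
#' @param net a `regnet`
#' @param params `node_params`
#' @param scenario_id 1, 2 or 3
#' @param alpha t-test significance level
#' @param solver a `solver_config`
#' @return list: `scenario`, `oa_ss`, `treated_ss`, `ttest`, `deltas`
#'   (treated minus OA, named vector)
#' @export
acs_scenario <- function(net, params, scenario_id, alpha = 0.05,
                         solver = solver_config()) {
  stopifnot(scenario_id %in% 1:3)
  require_nodes(net, c(OA_CYTOKINES, ACS_NODES))
  oa_ss <- oa_induction(net, params, solver)

  clamps <- c(stats::setNames(rep(1, length(ACS_NODES)), ACS_NODES), IL1B = 0)
  catabolic <- setdiff(OA_CYTOKINES, "IL1B")
  if (scenario_id == 2) clamps <- c(clamps, stats::setNames(rep(1, 5), catabolic))
  if (scenario_id == 3) clamps <- c(clamps, stats::setNames(rep(0.5, 5), catabolic))

  init <- oa_ss$x_star[setdiff(net$nodes$id, names(clamps))]
  pert <- perturbation(initial = init, clamps = clamps)
  treated <- integrate_to_steady_state(net, params, pert, solver)
  tt <- steady_state_ttest(oa_ss, treated, alpha)
  list(scenario = paste0("acs", scenario_id), oa_ss = oa_ss,
       treated_ss = treated, ttest = tt,
       deltas = treated$x_star - oa_ss$x_star)
}

#' Run a suite of treatment scenarios and write reports
#'
#' Runs the named built-in scenarios (`"acs1"`, `"acs2"`, `"acs3"`), writing
#' per-scenario steady-state CSVs, delta tables, a t-test summary, and a
#' bar-chart figure of OA vs treated activation. Failures in one scenario
#' are recorded and the suite continues.
#'
#' @param net a `regnet`
#' @param params `node_params`
#' @param scenarios character vector of scenario names (may be empty)
#' @param out_dir output directory (created if needed)
#' @param alpha t-test level
#' @param solver a `solver_config`
#' @param plot write PNG bar charts (default TRUE)
#' @return data.frame report, one row per scenario
#' @export
run_scenario_suite <- function(net, params, scenarios = c("acs1", "acs2", "acs3"),
                               out_dir, alpha = 0.05, solver = solver_config(),
                               plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(scenarios, function(sc) {
    sid <- suppressWarnings(as.integer(sub("^acs", "", sc)))
    res <- tryCatch({
      if (is.na(sid) || !(sid %in% 1:3)) stop("unknown scenario: ", sc)
      acs_scenario(net, params, sid, alpha, solver)
    }, error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(scenario = sc, ok = FALSE, p_value = NA_real_,
                        significant = NA, error = conditionMessage(res)))
    write_state_csv(res$oa_ss, file.path(out_dir, paste0(sc, "_oa_ss.csv")))
    write_state_csv(res$treated_ss, file.path(out_dir, paste0(sc, "_treated_ss.csv")))
    utils::write.csv(data.frame(node = names(res$deltas), delta = unname(res$deltas)),
                     file.path(out_dir, paste0(sc, "_deltas.csv")), row.names = FALSE)
    if (plot) scenario_barplot(res, file.path(out_dir, paste0(sc, "_barplot.png")))
    data.frame(scenario = sc, ok = TRUE, p_value = res$ttest$p_value,
               significant = res$ttest$significant, error = NA_character_)
  })
  report <- if (length(rows) == 0)
    data.frame(scenario = character(), ok = logical(), p_value = numeric(),
               significant = logical(), error = character())
  else do.call(rbind, rows)
  utils::write.csv(report, file.path(out_dir, "scenario_ttests.csv"), row.names = FALSE)
  report
}

scenario_barplot <- function(res, path) {
  grDevices::png(path, width = 1200, height = 500)
  on.exit(grDevices::dev.off())
  m <- rbind(OA = res$oa_ss$x_star, treated = res$treated_ss$x_star)
  graphics::barplot(m, beside = TRUE, las = 2, ylim = c(0, 1),
                    col = c("orange", "steelblue"),
                    main = paste0(res$scenario, " (p = ",
                                  signif(res$ttest$p_value, 3), ")"),
                    ylab = "steady-state activation")
  graphics::legend("topright", legend = rownames(m),
                   fill = c("orange", "steelblue"))
  invisible(path)
}
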