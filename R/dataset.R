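#' Perturbation-response dataset
#'
#' Container for the structure of multiplexed cytokine-release experiments: a
#' list of experiments, each with a perturbation (clamps and/or initial
#' overrides), measured per-node responses normalized to `[-1,1]`, and a mask
#' of node ids excluded from scoring. By convention every perturbed node that
#' is also measured is masked (the self-readout exclusion: a perturbed
#' protein's own readout carries no information about the network).
#'
#' @param experiments list of lists with elements `perturbation`
#'   (a [perturbation()]), `measured` (named numeric in `[-1,1]`), and
#'   optionally `mask` (character; self-readouts are added automatically)
#' @param auto_mask_self add perturbed-and-measured nodes to each mask
#'   (default TRUE)
#' @return object of class `perturbation_dataset`
#' @export
perturbation_dataset <- function(experiments, auto_mask_self = TRUE) {
  stopifnot(is.list(experiments), length(experiments) >= 1)
  experiments <- lapply(experiments, function(ex) {
    stopifnot(inherits(ex$perturbation, "perturbation"))
    m <- ex$measured
    if (is.null(names(m)) || any(names(m) == ""))
      stop("measured must be a named vector")
    if (any(m < -1 - 1e-9 | m > 1 + 1e-9)) stop("measured values must lie in [-1,1]")
    mask <- if (is.null(ex$mask)) character() else ex$mask
    if (auto_mask_self) {
      perturbed <- c(names(ex$perturbation$initial), names(ex$perturbation$clamps))
      mask <- union(mask, intersect(perturbed, names(m)))
    }
    bad <- setdiff(mask, names(m))
    if (length(bad) > 0) stop("mask names unmeasured node(s): ", paste(bad, collapse = ", "))
    list(perturbation = ex$perturbation, measured = m, mask = mask)
  })
  structure(list(experiments = experiments), class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  nn <- length(unique(unlist(lapply(x$experiments, function(e) names(e$measured)))))
  cat(sprintf("perturbation dataset: %d experiment(s), %d measured node(s)\n",
              length(x$experiments), nn))
  invisible(x)
}

fmt_pert <- function(p) {
  paste(c(if (length(p$clamps)) paste0("clamp:", names(p$clamps), "=",
                                       format(unname(p$clamps), digits = 15, trim = TRUE)),
          if (length(p$initial)) paste0("init:", names(p$initial), "=",
                                        format(unname(p$initial), digits = 15, trim = TRUE))),
        collapse = ";")
}

parse_pert <- function(s) {
  if (trimws(s) == "") return(perturbation())
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(clamp|init):([^=]+)=(.+)$", parts))
  bad <- vapply(m, length, 1L) != 4
  if (any(bad)) stop("malformed perturbation token(s): ",
                     paste(parts[bad], collapse = ", "))
  kind <- vapply(m, `[[`, "", 2); nodes <- vapply(m, `[[`, "", 3)
  vals <- as.numeric(vapply(m, `[[`, "", 4))
  perturbation(
    initial = if (any(kind == "init")) stats::setNames(vals[kind == "init"], nodes[kind == "init"]),
    clamps = if (any(kind == "clamp")) stats::setNames(vals[kind == "clamp"], nodes[kind == "clamp"]))
}

#' Read / write a perturbation-response dataset as CSV
#'
#' One row per experiment. First column `perturbation` holds semicolon-joined
#' `clamp:<node>=<value>` / `init:<node>=<value>` tokens; the remaining
#' columns are measured nodes. Masked cells carry the sentinel `NA!self`
#' (the value is written after the sentinel, `NA!self:<value>`, so the
#' round-trip is lossless); truly unmeasured cells are empty.
#'
#' @param path CSV file path
#' @param dataset a `perturbation_dataset`
#' @return `read_dataset`: a `perturbation_dataset`; `write_dataset`: `path`
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "perturbation")
    stop("dataset CSV must start with a 'perturbation' column")
  nodes <- names(df)[-1]
  experiments <- lapply(seq_len(nrow(df)), function(i) {
    pert <- parse_pert(df$perturbation[i])
    cells <- unlist(df[i, -1, drop = FALSE])
    present <- !is.na(cells) & cells != ""
    vals <- cells[present]
    msk <- startsWith(vals, "NA!self")
    num <- ifelse(msk, sub("^NA!self:?", "", vals), vals)
    num[num == ""] <- "0"     # bare sentinel: masked cell with unstated value
    measured <- stats::setNames(as.numeric(num), nodes[present])
    if (anyNA(measured)) stop("non-numeric measurement in row ", i)
    list(perturbation = pert, measured = measured, mask = nodes[present][msk])
  })
  perturbation_dataset(experiments, auto_mask_self = FALSE)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "perturbation_dataset"))
  nodes <- unique(unlist(lapply(dataset$experiments, function(e) names(e$measured))))
  rows <- vapply(dataset$experiments, function(ex) {
    cells <- vapply(nodes, function(nd) {
      if (!(nd %in% names(ex$measured))) return("")
      v <- format(unname(ex$measured[nd]), digits = 15, trim = TRUE)
      if (nd %in% ex$mask) paste0("NA!self:", v) else v
    }, character(1))
    paste(c(fmt_pert(ex$perturbation), cells), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("perturbation", nodes), collapse = ","), rows), path)
  invisible(path)
}

#' Read behavior rules from a semicolon-separated file
#'
#' Format: one rule per line, `stimulus;target;expected;citation`, where
#' `stimulus` uses the dataset-CSV perturbation token syntax with multiple
#' tokens joined by `,` (e.g. `clamp:IL1B=1,clamp:TNFA=1`) and `expected` is
#' `up`, `down`, or `unchanged`. Lines starting with `#` are ignored.
#'
#' @param path file path
#' @return list of [behavior_rule()] objects
#' @export
read_behavior_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], ";", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed rule on line ", i,
                            ": expected 'stimulus;target;expected;citation'")
    stim <- gsub(",", ";", trimws(f[1]), fixed = TRUE)
    behavior_rule(parse_pert(stim), trimws(f[2]), trimws(f[3]),
                  if (length(f) >= 4) trimws(f[4]) else "")
  })
}
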