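#' @useDynLib chondronet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

NODE_ROLES <- c("pro_inflammatory", "anti_inflammatory", "growth_factor",
                "degrading_enzyme", "structural_protein", "pain_related",
                "apoptosis_related", "other")

EDGE_SIGNS <- c("activation", "inhibition")
EDGE_PROVENANCE <- c("literature", "enrichment", "optimized", "synthetic")

# UniProt accession format (standard 6/10-character pattern)
UNIPROT_RE <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

#' Construct a signed regulatory network
#'
#' A `regnet` holds molecular nodes and signed, weighted, provenance-tagged
#' directed edges. Nodes are secreted regulators (cytokines, growth factors,
#' proteases, structural proteins); edges are activating or inhibiting
#' influences. Opposite-sign parallel edges between the same pair are allowed
#' (ambivalent regulation is biologically real) but surfaced as validation
#' warnings; exact duplicate (source, target, sign) triples are an error.
#'
#' @param nodes data.frame with columns `id`, and optionally `role`
#'   (one of `node_roles()`, default `"other"`) and `accession` (UniProt id or
#'   `NA`). May also be a character vector of ids.
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"activation"`/`"inhibition"` or `"+"`/`"-"`), and optionally `weight`
#'   (positive, default 1), `provenance` (default `"literature"`), `mutable`
#'   (logical, default TRUE).
#' @return object of class `regnet`
#' @export
regnet <- function(nodes = character(), edges = NULL) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) > 0 && !("id" %in% names(nodes)))
    stop("nodes must have an 'id' column")
  if (is.null(nodes$id)) nodes$id <- character()
  nodes$id <- as.character(nodes$id)
  if (is.null(nodes$role)) nodes$role <- rep("other", nrow(nodes))
  nodes$role[is.na(nodes$role)] <- "other"
  if (is.null(nodes$accession)) nodes$accession <- rep(NA_character_, nrow(nodes))
  nodes$accession <- as.character(nodes$accession)
  nodes <- nodes[, c("id", "role", "accession")]

  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), weight = numeric(),
                        provenance = character(), mutable = logical(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    for (col in c("source", "target", "sign"))
      if (is.null(edges[[col]])) stop("edges must have a '", col, "' column")
    edges$sign <- canonical_sign(edges$sign)
    if (is.null(edges$weight)) edges$weight <- 1
    edges$weight[is.na(edges$weight)] <- 1
    if (is.null(edges$provenance)) edges$provenance <- "literature"
    edges$provenance[is.na(edges$provenance)] <- "literature"
    if (is.null(edges$mutable)) edges$mutable <- TRUE
    edges$mutable[is.na(edges$mutable)] <- TRUE
    edges$mutable <- as.logical(edges$mutable)
  } else {
    edges$weight <- numeric(); edges$provenance <- character(); edges$mutable <- logical()
  }
  edges <- edges[, c("source", "target", "sign", "weight", "provenance", "mutable")]

  # node set is the union of declared nodes and edge endpoints
  extra <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(extra) > 0) {
    nodes <- rbind(nodes, data.frame(id = extra, role = "other",
                                     accession = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node ids: ",
                                    paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_role <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad_role) > 0) stop("unknown node role(s): ", paste(bad_role, collapse = ", "))
  if (any(edges$weight <= 0)) stop("edge weights must be > 0")
  bad_prov <- setdiff(unique(edges$provenance), EDGE_PROVENANCE)
  if (length(bad_prov) > 0) stop("unknown provenance: ", paste(bad_prov, collapse = ", "))
  key <- paste(edges$source, edges$target, edges$sign)
  if (anyDuplicated(key))
    stop("duplicate (source, target, sign) triple(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

canonical_sign <- function(s) {
  s <- as.character(s)
  out <- ifelse(s %in% c("+", "activation", "activates", "1"), "activation",
         ifelse(s %in% c("-", "inhibition", "inhibits", "-1"), "inhibition", NA))
  if (anyNA(out)) stop("unknown sign token(s): ",
                       paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("regnet: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "activation"), sum(x$edges$sign == "inhibition")))
  invisible(x)
}

#' Recognized node roles
#' @return character vector of role names
#' @export
node_roles <- function() NODE_ROLES

#' Number of nodes / edges
#' @param net a `regnet`
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

sign_token <- function(sign) ifelse(sign == "activation", "+", "-")

#' Read a network from an edge-list file
#'
#' Two dialects are supported. `sif3`: whitespace/tab-separated
#' `source sign target` with sign `+` or `-`; lines starting with `#` are
#' ignored; lossy (no weights, roles, provenance). `tsv_extended`: a
#' tab-separated edge table with header
#' `source sign target weight provenance mutable`, optionally followed by a
#' `#nodes` section with header `id role accession`; round-trips a network
#' exactly.
#'
#' @param path file path
#' @param dialect `"sif3"` or `"tsv_extended"`
#' @return a validated `regnet`
#' @export
read_network <- function(path, dialect = c("sif3", "tsv_extended")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "sif3") read_sif3(lines, path) else read_tsv_extended(lines, path)
}

read_sif3 <- function(lines, path) {
  src <- character(); tgt <- character(); sgn <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) != 3)
      stop(sprintf("parse error in %s line %d: expected 'source sign target', got %d field(s)",
                   path, i, length(parts)))
    if (!(parts[2] %in% c("+", "-")))
      stop(sprintf("parse error in %s line %d: unknown sign token '%s'", path, i, parts[2]))
    src <- c(src, parts[1]); sgn <- c(sgn, parts[2]); tgt <- c(tgt, parts[3])
  }
  if (length(src) == 0) return(regnet())
  regnet(edges = data.frame(source = src, target = tgt, sign = sgn,
                            stringsAsFactors = FALSE))
}

read_tsv_extended <- function(lines, path) {
  nodes_at <- which(trimws(lines) == "#nodes")
  edge_lines <- if (length(nodes_at) > 0) lines[seq_len(nodes_at[1] - 1)] else lines
  node_lines <- if (length(nodes_at) > 0) lines[(nodes_at[1] + 1):length(lines)] else character()
  edge_lines <- edge_lines[trimws(edge_lines) != "" & !startsWith(trimws(edge_lines), "#")]
  node_lines <- node_lines[trimws(node_lines) != "" & !startsWith(trimws(node_lines), "#")]

  parse_block <- function(blk, expect, what) {
    if (length(blk) == 0) return(NULL)
    hdr <- strsplit(blk[1], "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, expect))
      stop(sprintf("parse error in %s: %s header must be '%s'", path, what,
                   paste(expect, collapse = "\\t")))
    if (length(blk) == 1) return(NULL)
    rows <- strsplit(blk[-1], "\t", fixed = TRUE)
    bad <- which(vapply(rows, length, 1L) != length(expect))
    if (length(bad) > 0)
      stop(sprintf("parse error in %s: %s row %d has %d field(s), expected %d",
                   path, what, bad[1], length(rows[[bad[1]]]), length(expect)))
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- expect
    df
  }
  ed <- parse_block(edge_lines, c("source", "sign", "target", "weight", "provenance", "mutable"),
                    "edge")
  nd <- parse_block(node_lines, c("id", "role", "accession"), "node")
  if (!is.null(ed)) {
    ed$weight <- as.numeric(ed$weight)
    if (anyNA(ed$weight)) stop("parse error in ", path, ": non-numeric weight")
    ed$mutable <- ed$mutable %in% c("TRUE", "true", "1")
    ed <- ed[, c("source", "target", "sign", "weight", "provenance", "mutable")]
  }
  if (!is.null(nd)) {
    nd$accession[nd$accession %in% c("NA", "")] <- NA_character_
    # declared node table restricts the universe: edge endpoints must resolve
    if (!is.null(ed)) {
      dangling <- setdiff(unique(c(ed$source, ed$target)), nd$id)
      if (length(dangling) > 0)
        stop("validation error in ", path, ": edge references undeclared node(s): ",
             paste(dangling, collapse = ", "))
    }
  }
  regnet(nodes = if (is.null(nd)) character() else nd, edges = ed)
}

#' Write a network to an edge-list file
#'
#' `tsv_extended` round-trips exactly (weights, provenance, roles, accessions);
#' `sif3` keeps topology and signs only.
#'
#' @param net a `regnet`
#' @param path output file path
#' @param dialect `"sif3"` or `"tsv_extended"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, dialect = c("sif3", "tsv_extended")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(net, "regnet"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  e <- net$edges
  if (dialect == "sif3") {
    writeLines(sprintf("%s %s %s", e$source, sign_token(e$sign), e$target), con)
  } else {
    writeLines("source\tsign\ttarget\tweight\tprovenance\tmutable", con)
    if (nrow(e) > 0)
      writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%s", e$source, sign_token(e$sign),
                         e$target, format(e$weight, digits = 15, trim = TRUE),
                         e$provenance, e$mutable), con)
    writeLines("#nodes", con)
    writeLines("id\trole\taccession", con)
    n <- net$nodes
    if (nrow(n) > 0)
      writeLines(sprintf("%s\t%s\t%s", n$id, n$role,
                         ifelse(is.na(n$accession), "NA", n$accession)), con)
  }
  invisible(path)
}

#' Merge two networks (enrichment)
#'
#' Union of node sets and edge sets; duplicate (source, target, sign) triples
#' collapse to the base copy. Edges present only in `addition` are re-tagged
#' with provenance `"enrichment"` — this is how database-derived interactions
#' are layered onto a literature-curated network. When the same (source,
#' target) pair carries opposite signs in the two inputs, `conflict_policy`
#' decides: keep both edges, keep the base sign only, or keep the addition
#' sign only. A merge report (added edges, conflicts) is attached as
#' `attr(result, "merge_report")`.
#'
#' @param base,addition `regnet` objects
#' @param conflict_policy one of `"keep_both"`, `"prefer_base"`,
#'   `"prefer_addition"`
#' @return merged `regnet` with a `merge_report` attribute
#' @export
merge_networks <- function(base, addition,
                           conflict_policy = c("keep_both", "prefer_base", "prefer_addition")) {
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(inherits(base, "regnet"), inherits(addition, "regnet"))
  nodes <- rbind(base$nodes, addition$nodes[!(addition$nodes$id %in% base$nodes$id), ])

  be <- base$edges; ae <- addition$edges
  bkey <- paste(be$source, be$target, be$sign)
  akey <- paste(ae$source, ae$target, ae$sign)
  new <- ae[!(akey %in% bkey), , drop = FALSE]
  if (nrow(new) > 0) new$provenance <- "enrichment"

  # opposite-sign conflicts on the same ordered pair, across the two inputs
  opp <- function(s) ifelse(s == "activation", "inhibition", "activation")
  conflict_mask <- paste(new$source, new$target, opp(new$sign)) %in% bkey
  conflicts <- new[conflict_mask, , drop = FALSE]

  if (conflict_policy == "prefer_base") {
    new <- new[!conflict_mask, , drop = FALSE]
  } else if (conflict_policy == "prefer_addition" && nrow(conflicts) > 0) {
    drop_key <- paste(conflicts$source, conflicts$target, opp(conflicts$sign))
    be <- be[!(bkey %in% drop_key), , drop = FALSE]
  }
  merged <- regnet(nodes = nodes, edges = rbind(be, new))
  attr(merged, "merge_report") <- list(
    added = new, n_added = nrow(new),
    conflicts = conflicts, n_conflicts = nrow(conflicts),
    policy = conflict_policy)
  merged
}

#' Validate a network
#'
#' Structural checks beyond the constructor's hard invariants. Errors:
#' dangling edge references, nonpositive weights, duplicate triples, malformed
#' UniProt accessions. Warnings (reported, never dropped): nodes with no
#' incoming edges (boundary inputs whose dynamic treatment is a solver
#' policy), self-loops (autocrine signaling — allowed), and node pairs
#' connected by both an activating and an inhibiting edge (ambivalent
#' regulation).
#'
#' @param net a `regnet`
#' @return object of class `regnet_validation` with `errors`, `warnings`,
#'   `no_incoming`, `self_loops`, `ambivalent_pairs`; `ok` is TRUE iff no
#'   errors
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "regnet"))
  errors <- character(); warnings <- character()
  n <- net$nodes; e <- net$edges

  dangling <- setdiff(unique(c(e$source, e$target)), n$id)
  if (length(dangling) > 0)
    errors <- c(errors, paste0("dangling edge reference: ", dangling))
  if (any(e$weight <= 0)) errors <- c(errors, "nonpositive edge weight")
  key <- paste(e$source, e$target, e$sign)
  if (anyDuplicated(key))
    errors <- c(errors, paste0("duplicate triple: ", unique(key[duplicated(key)])))
  has_acc <- !is.na(n$accession)
  bad_acc <- n$id[has_acc & !grepl(UNIPROT_RE, n$accession)]
  if (length(bad_acc) > 0)
    errors <- c(errors, paste0("malformed UniProt accession on node: ", bad_acc))

  no_in <- setdiff(n$id, unique(e$target))
  if (length(no_in) > 0)
    warnings <- c(warnings, paste0("no incoming edges: ", no_in))
  loops <- unique(e$source[e$source == e$target])
  if (length(loops) > 0)
    warnings <- c(warnings, paste0("self-loop: ", loops))
  pair <- paste(e$source, e$target)
  amb <- unique(pair[pair %in% pair[e$sign == "activation"] &
                     pair %in% pair[e$sign == "inhibition"]])
  if (length(amb) > 0)
    warnings <- c(warnings, paste0("opposite-sign parallel edges: ", amb))

  structure(list(errors = errors, warnings = warnings,
                 no_incoming = no_in, self_loops = loops,
                 ambivalent_pairs = amb, ok = length(errors) == 0),
            class = "regnet_validation")
}

#' @export
print.regnet_validation <- function(x, ...) {
  cat(sprintf("network validation: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (m in x$errors) cat("  ERROR: ", m, "\n", sep = "")
  for (m in x$warnings) cat("  warning: ", m, "\n", sep = "")
  invisible(x)
}

#' Alias table mapping display names to canonical node tokens
#'
#' Canonical ids are case-sensitive ASCII tokens (e.g. `IL1B`, not
#' IL-1β) so file formats stay stable; this table maps the common
#' display names to those tokens.
#'
#' @return data.frame with columns `alias`, `id`
#' @export
node_aliases <- function() {
  path <- system.file("extdata", "node_aliases.tsv", package = "chondronet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Incoming-edge summary used by the dynamics layer
#'
#' @param net a `regnet`
#' @return list with, per node: activator indices/weights and inhibitor
#'   indices/weights (indices into `net$nodes$id`)
#' @keywords internal
incoming_edges <- function(net) {
  ids <- net$nodes$id
  e <- net$edges
  si <- match(e$source, ids); ti <- match(e$target, ids)
  lapply(seq_along(ids), function(i) {
    act <- which(ti == i & e$sign == "activation")
    inh <- which(ti == i & e$sign == "inhibition")
    list(activators = si[act], alpha = e$weight[act],
         inhibitors = si[inh], beta = e$weight[inh])
  })
}
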