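#' Assemble a bait-prey network from scored records
#'
#' Builds one directed edge per significant (bait, prey, condition) triple.
#' Self-edges (the bait protein recovered in its own purification) are
#' excluded from the partner edge set but retained separately as a
#' purification-success annotation.
#'
#' @param records `enrichment_records` with ranks assigned (e.g. from
#'   [score_all()]), or a pre-built edge data.frame with columns `bait`,
#'   `prey`, `sulfur`, `pyruvate`, `rank`, `rescued`.
#' @return An object of class `bait_network`: a list with `edges` (data.frame
#'   bait, prey, sulfur, pyruvate, rank, rescued), `baits` (all bait genes,
#'   including those without surviving edges) and `self_edges`.
#' @export
build_network <- function(records) {
  if (inherits(records, "enrichment_records")) {
    sig <- records[records$significant, , drop = FALSE]
    if (nrow(sig) && anyNA(sig$rank)) {
      stop_validation("significant records lack ranks; run assign_ranks() first")
    }
    edges <- data.frame(
      bait = sig$bait_gene, prey = sig$protein_id,
      sulfur = sig$sulfur, pyruvate = sig$pyruvate,
      rank = as.integer(sig$rank), rescued = sig$rescued,
      stringsAsFactors = FALSE
    )
    baits <- unique(records$bait_gene)
  } else {
    edges <- as.data.frame(records)
    required <- c("bait", "prey", "sulfur", "pyruvate", "rank", "rescued")
    missing_cols <- setdiff(required, names(edges))
    if (length(missing_cols)) {
      stop_validation("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    edges <- edges[required]
    edges$rank <- as.integer(edges$rank)
    edges$sulfur <- parse_logical(edges$sulfur, "sulfur")
    edges$pyruvate <- parse_logical(edges$pyruvate, "pyruvate")
    edges$rescued <- parse_logical(edges$rescued, "rescued")
    baits <- unique(edges$bait)
  }
  if (nrow(edges) && (anyNA(edges$rank) || any(edges$rank < 1L | edges$rank > 5L))) {
    stop_validation("edge ranks must be integers in 1..5")
  }
  key <- paste(edges$bait, edges$prey, edges$sulfur, edges$pyruvate)
  if (anyDuplicated(key)) {
    stop_validation("duplicate (bait, prey, condition) edge: ", key[duplicated(key)][1L])
  }
  self <- edges$bait == edges$prey
  net <- structure(
    list(edges = edges[!self, , drop = FALSE],
         baits = sort(baits),
         self_edges = edges[self, , drop = FALSE]),
    class = "bait_network"
  )
  net$edges <- sort_edges(net$edges)
  rownames(net$edges) <- NULL
  net
}

sort_edges <- function(edges) {
  edges[order(edges$bait, edges$prey, !edges$sulfur, !edges$pyruvate), , drop = FALSE]
}

#' @export
print.bait_network <- function(x, ...) {
  cat(sprintf("Bait-prey network: %d baits, %d edges, %d distinct preys\n",
              length(x$baits), nrow(x$edges), length(unique(x$edges$prey))))
  if (nrow(x$self_edges)) {
    cat(sprintf("  baits recovered in their own purification: %d\n", nrow(x$self_edges)))
  }
  invisible(x)
}

#' Filter a network by minimum rank
#'
#' @param network `bait_network`.
#' @param min_rank integer in 1..5; edges with `rank >= min_rank` survive.
#'   Baits are retained as nodes even when all their edges are removed.
#' @return Filtered `bait_network`.
#' @export
filter_rank <- function(network, min_rank) {
  stopifnot(inherits(network, "bait_network"))
  if (!is.numeric(min_rank) || length(min_rank) != 1L || is.na(min_rank) ||
      min_rank != round(min_rank) || min_rank < 1 || min_rank > 5) {
    stop_validation("min_rank must be an integer in 1..5")
  }
  network$edges <- network$edges[network$edges$rank >= min_rank, , drop = FALSE]
  rownames(network$edges) <- NULL
  network
}

#' Define a protein-complex group
#'
#' @param name complex acronym (e.g. "VOR", "POR", "FDH").
#' @param members character vector of member bait gene identifiers.
#' @return An object of class `complex_group`.
#' @export
complex_group <- function(name, members) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("complex name must be a single non-empty string")
  }
  members <- unique(as.character(members))
  if (!length(members)) stop_validation("complex group '", name, "' has no members")
  structure(list(name = name, members = members), class = "complex_group")
}

#' Derive complex groups from a target table
#'
#' Splits the semicolon-separated `complex_acronym` column into one
#' [complex_group()] per acronym (a gene shared by two complexes, like the
#' common POR/VOR gamma subunit, belongs to both groups).
#'
#' @param targets a `target_table` (see [read_target_table()], [target_table()]).
#' @return Named list of `complex_group` objects.
#' @export
complex_groups <- function(targets) {
  stopifnot(inherits(targets, "target_table"))
  pairs <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    data.frame(gene = targets$gene_id[i],
               complex = strsplit(targets$complex_acronym[i], ";", fixed = TRUE)[[1L]],
               stringsAsFactors = FALSE)
  }))
  acronyms <- unique(pairs$complex)
  stats::setNames(
    lapply(acronyms, function(a) complex_group(a, pairs$gene[pairs$complex == a])),
    acronyms
  )
}

#' Reciprocal associations between two complexes
#'
#' Two complexes are reciprocally associated in a condition when some tagged
#' subunit of the first copurifies a protein encoded by a member of the
#' second AND some tagged subunit of the second copurifies a protein of the
#' first. Genes shared by both complexes (e.g. the gamma subunit common to
#' POR and VOR) are excluded from the test with a warning.
#'
#' @param network `bait_network`.
#' @param group_a,group_b [complex_group()] objects.
#' @param sulfur,pyruvate condition flags.
#' @return An object of class `reciprocity`: list with `group_a`, `group_b`,
#'   `reciprocal` (logical), the directed inter-complex edge sets `a_to_b`
#'   and `b_to_a`, `n_associations` (their total number) and
#'   `shared_excluded`.
#' @export
reciprocal_pairs <- function(network, group_a, group_b, sulfur, pyruvate) {
  stopifnot(inherits(network, "bait_network"),
            inherits(group_a, "complex_group"), inherits(group_b, "complex_group"))
  check_flag(sulfur, "sulfur"); check_flag(pyruvate, "pyruvate")
  shared <- intersect(group_a$members, group_b$members)
  if (length(shared)) {
    warning(sprintf("groups %s and %s share subunit(s) %s; excluded from the reciprocity test",
                    group_a$name, group_b$name, paste(shared, collapse = ", ")),
            call. = FALSE)
  }
  a_members <- setdiff(group_a$members, shared)
  b_members <- setdiff(group_b$members, shared)
  e <- network$edges
  e <- e[e$sulfur == sulfur & e$pyruvate == pyruvate, , drop = FALSE]
  a_to_b <- e[e$bait %in% a_members & e$prey %in% b_members, , drop = FALSE]
  b_to_a <- e[e$bait %in% b_members & e$prey %in% a_members, , drop = FALSE]
  structure(
    list(group_a = group_a$name, group_b = group_b$name,
         reciprocal = nrow(a_to_b) > 0L && nrow(b_to_a) > 0L,
         a_to_b = a_to_b, b_to_a = b_to_a,
         n_associations = nrow(a_to_b) + nrow(b_to_a),
         shared_excluded = shared),
    class = "reciprocity"
  )
}

#' @export
print.reciprocity <- function(x, ...) {
  cat(sprintf("%s <-> %s: %s (%d inter-complex association(s): %d %s->%s, %d %s->%s)\n",
              x$group_a, x$group_b,
              if (x$reciprocal) "reciprocal" else "not reciprocal",
              x$n_associations,
              nrow(x$a_to_b), x$group_a, x$group_b,
              nrow(x$b_to_a), x$group_b, x$group_a))
  if (length(x$shared_excluded)) {
    cat("  shared subunit(s) excluded:", paste(x$shared_excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Prey proteins shared by every complex group
#'
#' Returns the proteins that are a significant prey of at least one tagged
#' subunit of EVERY supplied group, in the stated condition.
#'
#' @param network `bait_network`.
#' @param groups list of at least two [complex_group()] objects.
#' @param sulfur,pyruvate condition flags.
#' @param min_rank only edges with `rank >= min_rank` count (default 1, i.e.
#'   any significant association).
#' @return Sorted character vector of shared prey identifiers.
#' @export
intersect_groups <- function(network, groups, sulfur, pyruvate, min_rank = 1L) {
  stopifnot(inherits(network, "bait_network"))
  if (!is.list(groups) || length(groups) < 2L) {
    stop_validation("intersect_groups needs at least two complex groups")
  }
  for (g in groups) {
    if (!inherits(g, "complex_group")) stop_validation("groups must be complex_group objects")
  }
  net <- filter_rank(network, min_rank)
  e <- net$edges
  e <- e[e$sulfur == sulfur & e$pyruvate == pyruvate, , drop = FALSE]
  prey_sets <- lapply(groups, function(g) unique(e$prey[e$bait %in% g$members]))
  sort(Reduce(intersect, prey_sets))
}

#' Export a bait-prey network
#'
#' Formats: `"tsv"` (edge table with header bait, prey, sulfur, pyruvate,
#' rank, rescued), `"sif"` (Cytoscape simple interaction format,
#' `bait<TAB>copurifies<TAB>prey`; baits without edges appear as bare node
#' lines) and `"graphml"` (via igraph, with rank, sulfur, pyruvate and
#' rescued as typed edge attributes and a boolean `is_bait` node attribute).
#' Output ordering is deterministic (sorted).
#'
#' @param network `bait_network`.
#' @param path output file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "bait_network"))
  if (length(format) == 1L && !format %in% c("tsv", "sif", "graphml")) {
    stop_validation("unknown network format: ", format)
  }
  format <- match.arg(format)
  edges <- sort_edges(network$edges)
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s\tcopurifies\t%s", edges$bait, edges$prey)
    lonely <- sort(setdiff(network$baits, edges$bait))
    writeLines(c(lines, lonely), path)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a bait-prey network to an igraph graph
#'
#' @param network `bait_network`.
#' @return A directed igraph graph with `is_bait` vertex attribute and
#'   `rank`, `sulfur`, `pyruvate`, `rescued` edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "bait_network"))
  edges <- sort_edges(network$edges)
  nodes <- sort(unique(c(network$baits, edges$bait, edges$prey)))
  vertices <- data.frame(name = nodes, is_bait = nodes %in% network$baits,
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    edges[c("bait", "prey", "rank", "sulfur", "pyruvate", "rescued")],
    directed = TRUE, vertices = vertices
  )
}

#' Import a bait-prey network
#'
#' Reads a network written by [export_network()] in `"tsv"` or `"graphml"`
#' format. GraphML import restores integer ranks and boolean condition flags
#' exactly.
#'
#' @param path input file.
#' @param format `"tsv"` or `"graphml"`.
#' @return A `bait_network`.
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  if (length(format) == 1L && !format %in% c("tsv", "graphml")) {
    stop_validation("unknown network format: ", format)
  }
  format <- match.arg(format)
  check_file_exists(path)
  if (format == "tsv") {
    edges <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    return(build_network(edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(
    bait = el[, 1L], prey = el[, 2L],
    sulfur = as.logical(ea$sulfur), pyruvate = as.logical(ea$pyruvate),
    rank = as.integer(ea$rank), rescued = as.logical(ea$rescued),
    stringsAsFactors = FALSE
  )
  baits <- igraph::V(g)$name[as.logical(igraph::V(g)$is_bait)]
  net <- build_network(edges)
  net$baits <- sort(unique(c(net$baits, baits)))
  net
}
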