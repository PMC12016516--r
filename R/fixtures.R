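#' Bundled target-protein table
#'
#' The 25 tagged redox-protein genes of the interactome study, with complex
#' acronyms (a semicolon separates the two complexes sharing the common
#' POR/VOR gamma-subunit gene), subunit labels and tag terminus (two OGOR
#' subunits tolerate only N-terminal tags).
#'
#' @return A `target_table` data.frame with 25 rows.
#' @export
#' @examples
#' tt <- target_table()
#' nrow(tt)
target_table <- function() {
  read_target_table(system.file("extdata", "target_genes.tsv",
                                package = "apmsrank", mustWork = TRUE))
}

#' Bundled shared-partner network
#'
#' A small published bait-prey edge set in the sulfur condition: one tagged
#' subunit each of the OGOR, MBS and FDH complexes connected to the eight
#' prey proteins all three complexes copurify (including ferredoxin 3,
#' TK2012, and the MBH [4Fe-4S] cluster-binding subunit MBH-N, TK2093), plus
#' one complex-specific prey per bait so group intersections are exercised
#' non-trivially. Prey annotations are carried in the `"annotations"`
#' attribute.
#'
#' @return A `bait_network`.
#' @export
#' @examples
#' net <- shared_partner_network()
#' intersect_groups(net,
#'   list(complex_group("OGOR", "TK1130"), complex_group("MBS", "TK1215"),
#'        complex_group("FDH", "TK2077")),
#'   sulfur = TRUE, pyruvate = TRUE)
shared_partner_network <- function() {
  path <- system.file("extdata", "shared_partner_edges.tsv",
                      package = "apmsrank", mustWork = TRUE)
  edges <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  net <- build_network(edges)
  attr(net, "annotations") <- unique(edges[c("prey", "prey_annotation")])
  net
}

#' Bundled fixtures as a pair
#'
#' Convenience accessor returning both packaged transcriptions: the
#' target-protein table and the shared-partner edge network.
#'
#' @return list with elements `targets` and `shared_partners`.
#' @export
fixture_tables <- function() {
  list(targets = target_table(), shared_partners = shared_partner_network())
}
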