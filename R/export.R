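network_edge_table <- function(g) {
  if (inherits(g, "chain_graph")) return(g$edges)
  if (inherits(g, "cooccur_network")) {
    adj <- g$adjacency
    ut <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    out <- data.frame(u = g$taxon_ids[ut[, 1]], v = g$taxon_ids[ut[, 2]],
                      weight = g$edge_weights[ut], stringsAsFactors = FALSE)
    out$sign <- ifelse(out$weight >= 0, "positive", "negative")
    out$kind <- rep("taxon-taxon", nrow(out))
    return(out)
  }
  stop("unsupported graph object")
}

network_node_table <- function(g, taxonomy = NULL) {
  if (inherits(g, "chain_graph")) {
    nodes <- data.frame(name = c(g$response_ids, g$predictor_ids),
                        kind = c(rep("taxon", length(g$response_ids)),
                                 rep("env", length(g$predictor_ids))),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(name = g$taxon_ids, kind = "taxon",
                        stringsAsFactors = FALSE)
  }
  nodes$phylum <- character(nrow(nodes))
  if (!is.null(taxonomy)) {
    hit <- match(nodes$name, taxonomy$taxon_id)
    nodes$phylum <- ifelse(is.na(hit), "", taxonomy$phylum[hit])
  }
  nodes
}

#' Export a network to GraphML or edge-list TSV
#'
#' Nodes carry their kind (`taxon`/`env`) and, when a taxonomy table is
#' supplied, the phylum label; edges carry weight, sign and kind. A
#' re-import of either format reproduces the edge set exactly.
#'
#' @param g a `cooccur_network` or `chain_graph`.
#' @param path output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param taxonomy optional taxonomy data.frame ([read_taxonomy()] schema).
#' @return `path`, invisibly.
#' @export
export_network <- function(g, path, format = c("edge_tsv", "graphml"),
                           taxonomy = NULL) {
  format <- match.arg(format)
  edges <- network_edge_table(g)
  nodes <- network_node_table(g, taxonomy)
  if (format == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = nodes)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network edge list written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return data.frame `u`, `v`, `weight`, `sign`, `kind`.
#' @export
import_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(u = "character", v = "character"))
    return(out)
  }
  ig <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(ig, what = "edges")
  names(el)[1:2] <- c("u", "v")
  el
}
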