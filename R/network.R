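#' Load a gene-lipid association table
#'
#' Rows of (gene, selector) pairs linking lipid-metabolizing enzymes to panel
#' species. A selector is an exact species name (`selector_type = "species"`),
#' a headgroup class (`"class"`) or a LIPID MAPS subclass code
#' (`"subclass"`); each row carries a provenance note. The packaged default
#' covers 15 genes with standard enzyme-substrate class annotations and is a
#' documented, editable synthetic stand-in for a full reaction-path mapping.
#'
#' @param path Path to a TSV with columns `gene`, `selector_type`,
#'   `selector_value`, `provenance`; `NULL` loads the packaged default.
#' @return A validated data frame of class `gene_lipid_table`.
#' @export
gene_lipid_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_lipid_associations.tsv",
                        package = "lipidshift")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "selector_type", "selector_value", "provenance")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gene-lipid table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !tab$selector_type %in% c("species", "class", "subclass")
  if (any(bad))
    stop("malformed selector type(s): ",
         paste(unique(tab$selector_type[bad]), collapse = ", "), call. = FALSE)
  if (any(tab$gene != toupper(tab$gene)))
    stop("gene symbols must be uppercase", call. = FALSE)
  class(tab) <- c("gene_lipid_table", "data.frame")
  tab
}

#' Map lipid species to candidate genes
#'
#' Resolves every selector of the association table against the given lipids
#' and emits one `(gene, lipid)` edge per match, duplicates collapsed.
#'
#' @param lipids Character vector of lipid names (parsed internally).
#' @param table A [gene_lipid_table()].
#' @return A data frame with columns `gene` and `lipid` (canonical species
#'   names).
#' @examples
#' map_lipids_to_genes(c("CAR 12:0", "CAR 10:0", "LPC 18:0"))
#' @export
map_lipids_to_genes <- function(lipids, table = gene_lipid_table()) {
  stopifnot(is.character(lipids), inherits(table, "gene_lipid_table"))
  parsed <- lapply(lipids, parse_lipid_name)
  info <- data.frame(
    name = vapply(parsed, `[[`, character(1), "name"),
    raw = lipids,
    cls = vapply(parsed, `[[`, character(1), "lipid_class"),
    subclass = vapply(parsed, `[[`, character(1), "subclass_code"),
    stringsAsFactors = FALSE)
  edges <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    hit <- switch(row$selector_type,
      species = info$name == parse_lipid_name(row$selector_value)$name,
      class = info$cls == row$selector_value,
      subclass = info$subclass == row$selector_value)
    if (any(hit)) data.frame(gene = row$gene, lipid = info$name[hit],
                             stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, edges)
  if (is.null(out)) out <- data.frame(gene = character(), lipid = character())
  unique(out)
}

#' Remove generic/uninformative nodes from an edge list
#'
#' @param edges Data frame with columns `gene` and `lipid`.
#' @param blocklist Character vector of node labels to drop; `NULL` loads the
#'   packaged default (which includes `"Carnicor"`).
#' @return The filtered edge list.
#' @export
filter_generic_nodes <- function(edges, blocklist = NULL) {
  stopifnot(all(c("gene", "lipid") %in% names(edges)))
  if (is.null(blocklist)) {
    path <- system.file("extdata", "node_blocklist.txt", package = "lipidshift")
    blocklist <- readLines(path)
    blocklist <- trimws(blocklist[!grepl("^\\s*(#|$)", blocklist)])
  }
  edges[!(edges$gene %in% blocklist | edges$lipid %in% blocklist), ,
        drop = FALSE]
}

#' Build the bipartite gene-lipid graph
#'
#' Nodes are partitioned into genes and lipids; only gene-lipid edges are
#' allowed. Degree centrality is `degree / (n - 1)` and node size scores are
#' the degrees min-max scaled to \[1, 10\] (all 5.5 when degrees are uniform).
#'
#' @param edges Data frame with columns `gene` and `lipid`.
#' @return A list of class `gene_lipid_graph` with `graph` (igraph object),
#'   `nodes` (data frame: `name`, `partition`, `degree`, `centrality`,
#'   `size`), and `edges`.
#' @export
build_gene_lipid_graph <- function(edges) {
  stopifnot(all(c("gene", "lipid") %in% names(edges)))
  genes <- unique(edges$gene); lipids <- unique(edges$lipid)
  overlap <- intersect(genes, lipids)
  if (length(overlap))
    stop("bipartite violation: label(s) appear in both partitions: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  if (nrow(edges) && any(edges$gene == edges$lipid))
    stop("bipartite violation: self-loop", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(genes, lipids),
                          partition = rep(c("gene", "lipid"),
                                          c(length(genes), length(lipids)))))
  deg <- igraph::degree(g)
  n <- igraph::vcount(g)
  centrality <- if (n > 1) deg / (n - 1) else deg * 0
  size <- if (n == 0) numeric(0)
          else if (diff(range(deg)) == 0) rep(5.5, n)
          else 1 + 9 * (deg - min(deg)) / diff(range(deg))
  nodes <- data.frame(name = igraph::V(g)$name,
                      partition = igraph::V(g)$partition,
                      degree = as.integer(deg), centrality = centrality,
                      size = size, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "gene_lipid_graph")
}

#' @export
print.gene_lipid_graph <- function(x, ...) {
  cat(sprintf("<gene_lipid_graph> %d genes, %d lipids, %d edges\n",
              sum(x$nodes$partition == "gene"),
              sum(x$nodes$partition == "lipid"), nrow(x$edges)))
  invisible(x)
}

#' Kamada-Kawai layout coordinates
#'
#' Deterministic (seeded) stress-minimizing 2D coordinates; a minimum
#' separation between distinct nodes is enforced post hoc by deterministic
#' jitter.
#'
#' @param g A `gene_lipid_graph`.
#' @param seed Integer seed.
#' @param min_sep Minimum allowed distance between two nodes.
#' @return The node table of `g` with added `x` and `y` columns.
#' @export
layout_coordinates <- function(g, seed = 1L, min_sep = 1e-6) {
  stopifnot(inherits(g, "gene_lipid_graph"))
  n <- nrow(g$nodes)
  if (n == 0L) return(cbind(g$nodes, x = numeric(0), y = numeric(0)))
  set.seed(as.integer(seed))
  xy <- igraph::layout_with_kk(g$graph, dim = 2)
  if (n == 1L) xy <- matrix(0, 1, 2)
  # enforce separation of coincident nodes with a deterministic spiral nudge
  repeat {
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    clash <- which(d < min_sep, arr.ind = TRUE)
    if (nrow(clash) == 0L) break
    i <- clash[1, 1]
    ang <- 2 * pi * i / n
    xy[i, ] <- xy[i, ] + min_sep * 2 * c(cos(ang), sin(ang))
  }
  out <- g$nodes
  out$x <- xy[, 1]; out$y <- xy[, 2]
  out
}
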