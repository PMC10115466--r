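#' Construct an intracellular PPI network for one cell type
#'
#' A `cell_network` holds one cell type's undirected intracellular
#' protein-protein interaction graph together with the subset of its proteins
#' flagged as contact proteins (membrane/secreted proteins that take part in
#' an intercellular ligand-receptor interaction). Edges are simple and
#' undirected: self-loops are dropped and the unordered pair \{A, B\} is
#' stored once regardless of input orientation or multiplicity.
#'
#' @param cell_label Short string naming the cell type (e.g. `"oligo"`).
#' @param edges Two-column character matrix or data frame of protein
#'   identifier pairs. May be `NULL` or zero rows for an edgeless network.
#' @param proteins Optional character vector of protein identifiers; the
#'   union of edge endpoints is always included. Use this to carry proteins
#'   with no recorded intracellular interaction.
#' @param contacts Character vector of contact-protein identifiers; must be a
#'   subset of the network's proteins.
#' @return An object of class `cell_network` with fields `cell_label`,
#'   `proteins`, `edges` (two-column character matrix, endpoints sorted
#'   within row, rows unique), `contacts` and `non_contacts`.
#' @examples
#' net <- cell_network("cellA", rbind(c("P1", "P2"), c("P2", "P3")))
#' net
#' @export
cell_network <- function(cell_label, edges = NULL, proteins = NULL,
                         contacts = character()) {
  stopifnot(is.character(cell_label), length(cell_label) == 1L,
            nzchar(cell_label))
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  if (nrow(em) > 0L) {
    if (any(!nzchar(em))) stop("empty protein identifier in edge list")
    keep <- em[, 1L] != em[, 2L]           # self-loops are not meaningful here
    em <- em[keep, , drop = FALSE]
    em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), ,
             drop = FALSE]
  }
  prot <- sort(unique(c(as.character(proteins), as.vector(em))))
  if (any(!nzchar(prot))) stop("empty protein identifier")
  contacts <- sort(unique(as.character(contacts)))
  if (!all(contacts %in% prot)) {
    stop("contacts not present in network: ",
         paste(setdiff(contacts, prot), collapse = ", "))
  }
  structure(
    list(cell_label = cell_label,
         proteins = prot,
         edges = unname(em),
         contacts = contacts,
         non_contacts = setdiff(prot, contacts)),
    class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf(
    "cell_network '%s': %d proteins, %d edges, %d contact proteins\n",
    x$cell_label, length(x$proteins), nrow(x$edges), length(x$contacts)))
  invisible(x)
}

#' Construct the bipartite intercellular network
#'
#' Holds the intercellular (ligand-receptor supported) interactions between
#' the contact proteins of two cells. Its edge set E doubles as the candidate
#' bridge pair set P: only connected contact-protein pairs are eligible for
#' selection. Endpoints are cell-tagged: the same gene symbol occurring in
#' both cells denotes two distinct proteins.
#'
#' @param cell1_label,cell2_label Short strings naming the two cell types.
#' @param edges Two-column character matrix/data frame; column 1 holds cell-1
#'   proteins, column 2 cell-2 proteins. Duplicates are removed; order of
#'   first appearance is kept, then rows are sorted lexicographically for a
#'   canonical pair indexing.
#' @return Object of class `inter_network` with fields `cell1_label`,
#'   `cell2_label`, `edges`.
#' @export
inter_network <- function(cell1_label, cell2_label, edges) {
  stopifnot(nzchar(cell1_label), nzchar(cell2_label))
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(em) <- "character"
  if (nrow(em) > 0L) {
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), ,
             drop = FALSE]
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  structure(
    list(cell1_label = cell1_label, cell2_label = cell2_label,
         edges = unname(em)),
    class = "inter_network")
}

#' @export
print.inter_network <- function(x, ...) {
  cat(sprintf("inter_network %s--%s: %d intercellular interactions\n",
              x$cell1_label, x$cell2_label, nrow(x$edges)))
  invisible(x)
}

#' Read an undirected PPI edge list from a TSV file
#'
#' Expects two tab-separated protein-identifier columns per row; lines
#' starting with `#` and blank lines are ignored. Duplicate edges (in either
#' orientation) are collapsed and self-loop rows are dropped with a message
#' reporting the count.
#'
#' @param path Path to the edge-list file.
#' @param cell_label Cell-type label for the resulting network.
#' @return A [cell_network].
#' @export
read_edge_list <- function(path, cell_label) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list line %d in %s: expected 2 tab-separated fields",
                 idx[bad[1L]], path))
  }
  em <- t(vapply(fields, function(f) f[1:2], character(2L)))
  n_self <- sum(em[, 1L] == em[, 2L])
  if (n_self > 0L) {
    message(sprintf("%s: dropped %d self-loop row(s)", path, n_self))
  }
  # self-loop rows are dropped as edges but their protein is kept as a node
  cell_network(cell_label, em, proteins = unique(as.vector(em)))
}

#' Write a cell network's edge list to a TSV file
#'
#' Inverse of [read_edge_list()] up to edge canonicalization: reading the
#' written file reproduces the network's deduplicated undirected edge set.
#'
#' @param network A [cell_network].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "cell_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a proteome membership list (one identifier per line)
#'
#' @param path Path to the list; `#` comments and blank lines ignored.
#' @return Character vector of unique identifiers.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("proteome file not found: ", path)
  lines <- trimws(readLines(path))
  ids <- lines[!grepl("^(#|$)", lines)]
  unique(ids)
}

#' Read a ligand-receptor pair table (two tab-separated identifier columns)
#'
#' Pair orientation carries no meaning downstream: both orientations are
#' tested against both cells by [identify_contacts()].
#'
#' @param path Path to the TSV table; `#` comments and blank lines ignored.
#' @return Two-column character matrix of partner identifiers.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) stop("ligand-receptor table not found: ", path)
  lines <- readLines(path)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(idx) == 0L) stop("empty ligand-receptor table: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed ligand-receptor line %d in %s", idx[bad[1L]], path))
  }
  t(vapply(fields, function(f) f[1:2], character(2L)))
}

#' Restrict a network to a proteome
#'
#' Induced subgraph on the intersection of the network's proteins with the
#' given proteome; an edge survives iff both endpoints do.
#'
#' @param network A [cell_network].
#' @param proteome Character vector of protein identifiers to keep.
#' @return The restricted [cell_network].
#' @export
restrict_to_proteome <- function(network, proteome) {
  stopifnot(inherits(network, "cell_network"))
  keep <- intersect(network$proteins, proteome)
  if (length(keep) == 0L) {
    stop("proteome restriction leaves an empty network (identifier namespaces may differ)")
  }
  em <- network$edges
  em <- em[em[, 1L] %in% keep & em[, 2L] %in% keep, , drop = FALSE]
  cell_network(network$cell_label, em, proteins = keep,
               contacts = intersect(network$contacts, keep))
}

#' Identify contact proteins and the intercellular network
#'
#' Maps a ligand-receptor pair table onto the proteomes of two cells:
#' an intercellular edge (u, v) is created whenever some ligand-receptor pair
#' places u in cell 1's proteome and v in cell 2's proteome, in either
#' orientation of the pair (intercellular edges are undirected; ligand or
#' receptor role is ignored). The endpoints each cell contributes become its
#' contact proteins, and the contact flags are written back into the returned
#' cell networks.
#'
#' @param net1,net2 [cell_network] objects for the two cells.
#' @param lr_pairs Two-column character matrix of ligand-receptor partner
#'   identifiers (see [read_lr_pairs()]).
#' @return List with elements `net1`, `net2` (contact-flagged networks) and
#'   `inter` (the [inter_network]).
#' @examples
#' n1 <- cell_network("a", rbind(c("P1", "P2")))
#' n2 <- cell_network("b", rbind(c("Q1", "Q2")))
#' res <- identify_contacts(n1, n2, rbind(c("P1", "Q1")))
#' res$inter
#' @export
identify_contacts <- function(net1, net2, lr_pairs) {
  stopifnot(inherits(net1, "cell_network"), inherits(net2, "cell_network"))
  lr <- as.matrix(lr_pairs)[, 1:2, drop = FALSE]
  storage.mode(lr) <- "character"
  # both orientations: partner_a in cell1 & partner_b in cell2, and vice versa
  fwd <- lr[lr[, 1L] %in% net1$proteins & lr[, 2L] %in% net2$proteins, ,
            drop = FALSE]
  rev <- lr[lr[, 2L] %in% net1$proteins & lr[, 1L] %in% net2$proteins,
            c(2L, 1L), drop = FALSE]
  em <- rbind(fwd, rev)
  if (nrow(em) == 0L) {
    stop("no intercellular interactions found; check that the ligand-receptor ",
         "table and the proteomes use the same identifier namespace")
  }
  inter <- inter_network(net1$cell_label, net2$cell_label, em)
  c1 <- unique(inter$edges[, 1L])
  c2 <- unique(inter$edges[, 2L])
  net1 <- cell_network(net1$cell_label, net1$edges, proteins = net1$proteins,
                       contacts = c1)
  net2 <- cell_network(net2$cell_label, net2$edges, proteins = net2$proteins,
                       contacts = c2)
  list(net1 = net1, net2 = net2, inter = inter)
}

#' Drop proteins with no intracellular interaction
#'
#' Removes degree-0 nodes from the intracellular graph. A dropped contact
#' protein loses its intracellular contact flag but may still appear in an
#' intercellular network; downstream scoring assigns it a floor importance so
#' it remains selectable.
#'
#' @param network A [cell_network].
#' @return The pruned [cell_network].
#' @export
remove_unconnected <- function(network) {
  stopifnot(inherits(network, "cell_network"))
  connected <- unique(as.vector(network$edges))
  cell_network(network$cell_label, network$edges,
               proteins = connected,
               contacts = intersect(network$contacts, connected))
}

# igraph view of the intracellular graph; vertex names = protein ids
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$proteins, stringsAsFactors = FALSE))
}
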