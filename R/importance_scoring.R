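#' PageRank centrality by power iteration
#'
#' Synchronous power iteration on the undirected intracellular graph treated
#' as bidirectional. Scores start uniform and are updated as
#' `p' = (1 - d)/N + d * sum_{u ~ v} p_u / deg(u)`, with the mass of
#' degree-0 nodes redistributed uniformly. Iteration stops when the L1 change
#' across nodes in one sweep falls below `epsilon`; the final vector is
#' renormalized to sum to 1. Defaults (damping 0.85, epsilon 0.001) match the
#' widely used network-analysis tool defaults so scores are comparable across
#' implementations.
#'
#' @param network A [cell_network]; must contain at least one protein.
#' @param damping Damping factor d in (0, 1).
#' @param epsilon L1 convergence threshold per sweep.
#' @param max_iter Maximum number of sweeps before a convergence error.
#' @return A `centrality_table`: list with `cell_label`, `metric`
#'   (`"pagerank"`) and `scores`, a named non-negative vector summing to 1.
#' @examples
#' net <- cell_network("a", rbind(c("H", "L1"), c("H", "L2"), c("H", "L3")))
#' pagerank_centrality(net)$scores
#' @export
pagerank_centrality <- function(network, damping = 0.85, epsilon = 0.001,
                                max_iter = 1000L) {
  stopifnot(inherits(network, "cell_network"))
  n <- length(network$proteins)
  if (n == 0L) stop("cannot compute PageRank on an empty network")
  stopifnot(damping > 0, damping < 1, epsilon > 0)
  idx <- stats::setNames(seq_len(n), network$proteins)
  i <- idx[network$edges[, 1L]]
  j <- idx[network$edges[, 2L]]
  deg <- tabulate(c(i, j), nbins = n)
  dangling <- deg == 0L
  p <- rep(1 / n, n)
  # neighbor-summed contributions via both edge directions
  src <- c(i, j)
  dst <- c(j, i)
  for (iter in seq_len(max_iter)) {
    w <- ifelse(dangling, 0, p / pmax(deg, 1L))
    spread <- numeric(n)
    if (length(src) > 0L) {
      agg <- rowsum(w[src], group = dst)
      spread[as.integer(rownames(agg))] <- agg[, 1L]
    }
    p_new <- (1 - damping) / n + damping * (spread + sum(p[dangling]) / n)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < epsilon) {
      p <- p / sum(p)
      return(structure(list(cell_label = network$cell_label,
                            metric = "pagerank",
                            scores = stats::setNames(p, network$proteins)),
                       class = "centrality_table"))
    }
  }
  stop(sprintf("PageRank did not converge within %d iterations", max_iter))
}

#' Betweenness centrality (Brandes)
#'
#' Unnormalized shortest-path betweenness on the undirected graph; each
#' unordered node pair is counted once. Computed with igraph's Brandes
#' implementation.
#'
#' @param network A [cell_network]; must contain at least one protein.
#' @return A `centrality_table` with `metric = "betweenness"`.
#' @export
betweenness_centrality <- function(network) {
  stopifnot(inherits(network, "cell_network"))
  if (length(network$proteins) == 0L) {
    stop("cannot compute betweenness on an empty network")
  }
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  structure(list(cell_label = network$cell_label,
                 metric = "betweenness",
                 scores = b[network$proteins]),
            class = "centrality_table")
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("centrality_table '%s' (%s): %d proteins\n",
              x$cell_label, x$metric, length(x$scores)))
  invisible(x)
}

#' The two pruned distance networks used by the IIS
#'
#' The importance score measures each contact protein's closeness to the rest
#' of the cell on two deliberately pruned graphs, so that contact-contact
#' shortcuts do not blur the distances to intracellular (non-contact)
#' proteins:
#' * `noncontact_paths`: all nodes, with every edge joining two contact
#'   proteins removed — the graph on which distances to non-contact proteins
#'   are measured;
#' * `contact_only`: the induced subgraph on the contact proteins — the graph
#'   on which contact-to-contact distances are measured.
#'
#' @param network A [cell_network] with contacts flagged.
#' @return List with [cell_network] elements `noncontact_paths` and
#'   `contact_only`.
#' @export
pruned_distance_graphs <- function(network) {
  stopifnot(inherits(network, "cell_network"))
  em <- network$edges
  cc <- em[, 1L] %in% network$contacts & em[, 2L] %in% network$contacts
  g1 <- cell_network(network$cell_label, em[!cc, , drop = FALSE],
                     proteins = network$proteins,
                     contacts = network$contacts)
  g2 <- cell_network(network$cell_label, em[cc, , drop = FALSE],
                     proteins = network$contacts,
                     contacts = network$contacts)
  list(noncontact_paths = g1, contact_only = g2)
}

#' Intracellular importance scores (IIS) for contact proteins
#'
#' For each contact protein i the IIS is
#' `sum_j PR_j / d_ij + sum_k PR_k / d_ik`, where j ranges over the
#' non-contact proteins reachable from i on the contact-contact-pruned graph,
#' k over the other contact proteins reachable from i on the contact-only
#' graph, `PR` is the centrality score, and `d` the breadth-first-search hop
#' distance on the respective pruned graph. Unreachable proteins contribute
#' nothing. The per-protein additive terms are recorded so the top score
#' contributors can be reported.
#'
#' @param network A [cell_network] with contacts flagged.
#' @param centrality A `centrality_table` covering all proteins of the
#'   network (see [pagerank_centrality()], [betweenness_centrality()]).
#' @return An `iis_table`: list with `cell_label`, `metric`, `raw` (named
#'   numeric over contacts), `normalized` (`NULL` until [normalize_iis()]),
#'   and `contributions` (per contact, a named vector of additive terms).
#' @export
compute_iis <- function(network, centrality) {
  stopifnot(inherits(network, "cell_network"),
            inherits(centrality, "centrality_table"))
  contacts <- network$contacts
  missing_scores <- setdiff(network$proteins, names(centrality$scores))
  if (length(missing_scores) > 0L) {
    stop("centrality table lacks scores for: ",
         paste(utils::head(missing_scores, 5L), collapse = ", "))
  }
  pr <- centrality$scores
  pruned <- pruned_distance_graphs(network)
  raw <- stats::setNames(numeric(length(contacts)), contacts)
  contributions <- stats::setNames(vector("list", length(contacts)), contacts)
  if (length(contacts) > 0L) {
    d1 <- graph_distances(pruned$noncontact_paths, from = contacts)
    d2 <- graph_distances(pruned$contact_only, from = contacts)
    nc <- network$non_contacts
    for (i in contacts) {
      terms <- numeric(0)
      if (length(nc) > 0L) {
        di <- d1[i, nc]
        reach <- is.finite(di) & di > 0
        terms <- pr[nc[reach]] / di[reach]
      }
      others <- setdiff(contacts, i)
      if (length(others) > 0L) {
        dk <- d2[i, others]
        reach <- is.finite(dk) & dk > 0
        terms <- c(terms, pr[others[reach]] / dk[reach])
      }
      raw[[i]] <- sum(terms)
      contributions[[i]] <- terms
    }
  }
  structure(list(cell_label = network$cell_label,
                 metric = centrality$metric,
                 raw = raw,
                 normalized = NULL,
                 contributions = contributions),
            class = "iis_table")
}

# hop-count distance matrix rows = `from`, columns = all proteins
graph_distances <- function(network, from) {
  if (length(network$proteins) == 0L || length(from) == 0L) {
    return(matrix(Inf, nrow = length(from), ncol = 0L,
                  dimnames = list(from, NULL)))
  }
  g <- as_igraph(network)
  d <- igraph::distances(g, v = from, to = igraph::V(g), weights = NA)
  colnames(d) <- igraph::V(g)$name
  rownames(d) <- from
  d
}

#' Normalize IIS to the per-cell maximum
#'
#' Each raw score is divided by the cell's maximum raw score, then floored at
#' a small positive `floor`. Max-scaling (rather than min-max) preserves the
#' ordering and keeps every score strictly positive, so the inverse-sum pair
#' costs used by the bridge optimizer stay finite; the floor keeps contact
#' proteins with zero intracellular importance (e.g. intracellularly isolated
#' ones) selectable at a very high, but finite, cost.
#'
#' @param table An `iis_table` from [compute_iis()].
#' @param floor Positive lower bound applied after scaling.
#' @return The `iis_table` with its `normalized` field filled in.
#' @export
normalize_iis <- function(table, floor = 1e-9) {
  stopifnot(inherits(table, "iis_table"), floor > 0)
  if (length(table$raw) == 0L || max(table$raw) <= 0) {
    stop("cannot normalize: no contact protein has a positive raw IIS")
  }
  table$normalized <- pmax(table$raw / max(table$raw), floor)
  table
}

#' @export
print.iis_table <- function(x, ...) {
  cat(sprintf("iis_table '%s' (%s): %d contact proteins%s\n",
              x$cell_label, x$metric, length(x$raw),
              if (is.null(x$normalized)) " (not normalized)" else ""))
  invisible(x)
}

#' Top score contributors for a contact protein
#'
#' Ranks the intracellular proteins by their additive term `PR_j / d_ij` in
#' the given contact protein's IIS, descending; ties are broken
#' lexicographically by protein identifier so the ordering is stable.
#'
#' @param table An `iis_table`.
#' @param protein Contact-protein identifier present in the table.
#' @param k Maximum number of contributors to return.
#' @return Data frame with columns `contributor` and `contribution`, at most
#'   `k` rows.
#' @export
top_contributors <- function(table, protein, k = 20L) {
  stopifnot(inherits(table, "iis_table"))
  if (!protein %in% names(table$contributions)) {
    stop("unknown contact protein: ", protein)
  }
  contr <- table$contributions[[protein]]
  ord <- order(-contr, names(contr))
  out <- data.frame(contributor = names(contr)[ord],
                    contribution = unname(contr[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Export an IIS table as TSV
#'
#' Columns: `cell`, `protein`, `raw_iis`, `normalized_iis`.
#'
#' @param table A normalized `iis_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iis_table <- function(table, path) {
  stopifnot(inherits(table, "iis_table"))
  if (is.null(table$normalized)) stop("normalize the table before export")
  prot <- sort(names(table$raw))
  df <- data.frame(cell = table$cell_label,
                   protein = prot,
                   raw_iis = format_num(table$raw[prot]),
                   normalized_iis = format_num(table$normalized[prot]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IIS table written by [write_iis_table()]
#'
#' Contributor terms are not round-tripped; the re-read table carries raw and
#' normalized scores only, which is all the bridge step needs.
#'
#' @param path Path to the TSV file.
#' @param metric Metric tag to attach (not stored in the file).
#' @return An `iis_table`.
#' @export
read_iis_table <- function(path, metric = "pagerank") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  structure(list(cell_label = df$cell[1L],
                 metric = metric,
                 raw = stats::setNames(as.numeric(df$raw_iis), df$protein),
                 normalized = stats::setNames(as.numeric(df$normalized_iis),
                                              df$protein),
                 contributions = NULL),
            class = "iis_table")
}

#' Export per-contact-protein score contributors as TSV
#'
#' Columns: `cell`, `contact_protein`, `contributor`, `contribution`; rows
#' ordered by contact protein, then contribution descending (ties
#' lexicographic), truncated to the top `k` per contact protein.
#'
#' @param table An `iis_table` with contributions.
#' @param path Output path.
#' @param k Contributors kept per contact protein.
#' @return `path`, invisibly.
#' @export
write_contributors <- function(table, path, k = 20L) {
  stopifnot(inherits(table, "iis_table"), !is.null(table$contributions))
  rows <- lapply(sort(names(table$contributions)), function(p) {
    tc <- top_contributors(table, p, k)
    if (nrow(tc) == 0L) return(NULL)
    data.frame(cell = table$cell_label, contact_protein = p,
               contributor = tc$contributor,
               contribution = format_num(tc$contribution),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(cell = character(), contact_protein = character(),
                     contributor = character(), contribution = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-width numeric formatting so identical runs give identical bytes
format_num <- function(x) sprintf("%.12g", x)
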