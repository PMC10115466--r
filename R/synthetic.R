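#' Specification for a synthetic two-cell interactome
#'
#' Describes a desk-scale pair of intracellular PPI networks plus a bipartite
#' intercellular contact network, with a small set of "planted" bridge
#' proteins given boosted intracellular connectivity and several
#' intercellular interactions — an operational ground truth for recovery
#' experiments. Defaults give hub-dominated (preferential-attachment)
#' intracellular topology with edge density and contact fractions in the
#' range typical of curated PPI/ligand-receptor compilations, at a size every
#' pipeline stage can process in seconds.
#'
#' @param n1,n2 Protein counts of the two cells.
#' @param m1,m2 Intracellular edge counts (before planted-bridge wiring,
#'   which may add a few extra edges).
#' @param contact_frac1,contact_frac2 Fraction of each cell's proteins
#'   eligible to be contact proteins, in (0, 1].
#' @param inter_edges Number of intercellular interactions.
#' @param topology `"preferential_attachment"` (hubby, small-world-like) or
#'   `"erdos_renyi"`.
#' @param planted_bridge_count Number of planted bridge proteins per cell.
#' @param seed Integer seed making generation reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n1 = 60L, n2 = 50L, m1 = 180L, m2 = 150L,
                           contact_frac1 = 0.25, contact_frac2 = 0.25,
                           inter_edges = 40L,
                           topology = c("preferential_attachment",
                                        "erdos_renyi"),
                           planted_bridge_count = 2L, seed = 1L) {
  topology <- match.arg(topology)
  spec <- list(n1 = as.integer(n1), n2 = as.integer(n2),
               m1 = as.integer(m1), m2 = as.integer(m2),
               contact_frac1 = contact_frac1, contact_frac2 = contact_frac2,
               inter_edges = as.integer(inter_edges), topology = topology,
               planted_bridge_count = as.integer(planted_bridge_count),
               seed = as.integer(seed))
  c1 <- max(1L, round(spec$contact_frac1 * spec$n1))
  c2 <- max(1L, round(spec$contact_frac2 * spec$n2))
  if (spec$m1 > spec$n1 * (spec$n1 - 1) / 2 ||
      spec$m2 > spec$n2 * (spec$n2 - 1) / 2) {
    stop("requested edge count exceeds simple-graph capacity")
  }
  if (spec$contact_frac1 <= 0 || spec$contact_frac1 > 1 ||
      spec$contact_frac2 <= 0 || spec$contact_frac2 > 1) {
    stop("contact fractions must lie in (0, 1]")
  }
  if (spec$inter_edges > c1 * c2) {
    stop("inter_edges exceeds the number of possible contact pairs")
  }
  if (spec$inter_edges < 1L) stop("at least one intercellular edge required")
  if (spec$planted_bridge_count > min(c1, c2)) {
    stop("more planted bridges than contact proteins")
  }
  structure(spec, class = "synthetic_spec")
}

# simple undirected graph with exactly m edges on ids; preferential
# attachment biases one endpoint by degree + 1, producing hubs
random_simple_graph <- function(ids, m, topology) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  deg <- integer(n)
  edges <- matrix(integer(), ncol = 2L)
  attempts <- 0L
  while (nrow(edges) < m) {
    if (topology == "preferential_attachment") {
      u <- sample.int(n, 1L)
      v <- sample.int(n, 1L, prob = deg + 1)
    } else {
      uv <- sample.int(n, 2L)
      u <- uv[1L]; v <- uv[2L]
    }
    attempts <- attempts + 1L
    if (u == v || adj[u, v]) {
      if (attempts > 100L * m) {   # dense corner: fill from the missing pairs
        missing <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
        need <- m - nrow(edges)
        pick <- missing[sample.int(nrow(missing), need), , drop = FALSE]
        for (r in seq_len(need)) {
          adj[pick[r, 1L], pick[r, 2L]] <- adj[pick[r, 2L], pick[r, 1L]] <- TRUE
        }
        edges <- rbind(edges, pick)
        break
      }
      next
    }
    adj[u, v] <- adj[v, u] <- TRUE
    deg[u] <- deg[u] + 1L
    deg[v] <- deg[v] + 1L
    edges <- rbind(edges, c(u, v))
  }
  list(edges = cbind(ids[edges[, 1L]], ids[edges[, 2L]]), adj = adj,
       deg = deg)
}

#' Generate a synthetic two-cell interactome
#'
#' Builds the two intracellular networks, designates contact-eligible
#' proteins, wires the intercellular network over them, and plants the
#' ground-truth bridges: each planted contact protein is additionally
#' connected to the cell's highest-degree non-contact proteins (raising its
#' IIS) and receives several intercellular edges (raising its coverage
#' degree), so a correct pipeline should prefer it. Contact flags in the
#' returned networks are the intercellular-edge endpoints, exactly as
#' [identify_contacts()] would assign them from the written input files.
#'
#' @param spec A [synthetic_spec].
#' @return Object of class `synthetic_interactome`: list with `net1`, `net2`
#'   ([cell_network]s), `inter` ([inter_network]), `ground_truth` (list of
#'   planted protein ids `cell1`, `cell2`), and `spec`.
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed, {
    ids1 <- sprintf("A%03d", seq_len(spec$n1))
    ids2 <- sprintf("B%03d", seq_len(spec$n2))
    g1 <- random_simple_graph(ids1, spec$m1, spec$topology)
    g2 <- random_simple_graph(ids2, spec$m2, spec$topology)
    c1 <- sort(sample(ids1, max(1L, round(spec$contact_frac1 * spec$n1))))
    c2 <- sort(sample(ids2, max(1L, round(spec$contact_frac2 * spec$n2))))
    planted1 <- sort(sample(c1, spec$planted_bridge_count))
    planted2 <- sort(sample(c2, spec$planted_bridge_count))

    boost_wiring <- function(g, ids, planted, contacts, k_boost = 12L) {
      # planted bridges sit one hop from the cell's strongest non-contact
      # hubs (inflating the non-contact IIS term) and adjacent to several
      # fellow contacts (inflating the contact-graph term)
      noncontact <- setdiff(ids, contacts)
      hubs <- noncontact[order(-g$deg[match(noncontact, ids)])]
      hubs <- utils::head(hubs, k_boost)
      peers <- utils::head(setdiff(contacts, planted), 6L)
      extra <- do.call(rbind, lapply(planted, function(p) {
        cbind(p, c(hubs, peers))
      }))
      rbind(g$edges, extra)
    }
    edges1 <- boost_wiring(g1, ids1, planted1, c1)
    edges2 <- boost_wiring(g2, ids2, planted2, c2)

    # intercellular wiring: planted x planted pairs, extra planted-incident
    # edges, then uniform fill over the remaining contact pairs
    all_pairs <- expand.grid(a = c1, b = c2, stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
    key <- function(a, b) paste(a, b, sep = "\r")
    planted_pairs <- expand.grid(a = planted1, b = planted2,
                                 stringsAsFactors = FALSE,
                                 KEEP.OUT.ATTRS = FALSE)
    extra1 <- data.frame(a = rep(planted1, each = 3L),
                         b = sample(c2, 3L * length(planted1), replace = TRUE),
                         stringsAsFactors = FALSE)
    extra2 <- data.frame(a = sample(c1, 3L * length(planted2), replace = TRUE),
                         b = rep(planted2, each = 3L),
                         stringsAsFactors = FALSE)
    forced <- rbind(planted_pairs, extra1, extra2)
    forced <- forced[!duplicated(key(forced$a, forced$b)), , drop = FALSE]
    forced <- utils::head(forced, spec$inter_edges)
    pool <- all_pairs[!key(all_pairs$a, all_pairs$b) %in%
                        key(forced$a, forced$b), , drop = FALSE]
    need <- spec$inter_edges - nrow(forced)
    fill <- pool[sample.int(nrow(pool), need), , drop = FALSE]
    inter_e <- as.matrix(rbind(forced, fill))

    inter <- inter_network(spec$cell1_label %||% "cell_a",
                           spec$cell2_label %||% "cell_b", inter_e)
    net1 <- cell_network("cell_a", edges1, proteins = ids1,
                         contacts = unique(inter$edges[, 1L]))
    net2 <- cell_network("cell_b", edges2, proteins = ids2,
                         contacts = unique(inter$edges[, 2L]))
    structure(list(net1 = net1, net2 = net2, inter = inter,
                   ground_truth = list(cell1 = planted1, cell2 = planted2),
                   spec = spec),
              class = "synthetic_interactome")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_interactome <- function(x, ...) {
  cat(sprintf(
    "synthetic_interactome: %d + %d proteins, %d intercellular edges, %d + %d planted bridges (seed %d)\n",
    length(x$net1$proteins), length(x$net2$proteins), nrow(x$inter$edges),
    length(x$ground_truth$cell1), length(x$ground_truth$cell2), x$spec$seed))
  invisible(x)
}

#' Write a synthetic interactome in the pipeline's input formats
#'
#' Emits the same plain-text files [run_score()] consumes: two edge lists,
#' two proteome lists, the ligand-receptor table (one row per intercellular
#' edge), plus the planted ground truth (`ground_truth.tsv`, columns `cell`
#' and `protein`) and the generating spec (`spec.yaml`).
#'
#' @param sim A `synthetic_interactome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_interactome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges1 = file.path(dir, "edges_cell1.tsv"),
             edges2 = file.path(dir, "edges_cell2.tsv"),
             proteome1 = file.path(dir, "proteome_cell1.txt"),
             proteome2 = file.path(dir, "proteome_cell2.txt"),
             lr_pairs = file.path(dir, "lr_pairs.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"),
             spec = file.path(dir, "spec.yaml"))
  write_edge_list(sim$net1, paths[["edges1"]])
  write_edge_list(sim$net2, paths[["edges2"]])
  writeLines(sim$net1$proteins, paths[["proteome1"]])
  writeLines(sim$net2$proteins, paths[["proteome2"]])
  utils::write.table(sim$inter$edges, paths[["lr_pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gt <- data.frame(
    cell = rep(c(sim$net1$cell_label, sim$net2$cell_label),
               c(length(sim$ground_truth$cell1), length(sim$ground_truth$cell2))),
    protein = c(sim$ground_truth$cell1, sim$ground_truth$cell2))
  utils::write.table(gt, paths[["ground_truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(sim$spec), paths[["spec"]])
  invisible(paths)
}

#' Hand-built worked fixtures
#'
#' Small fully specified two-cell instances exercising particular behaviors:
#' * `"two_cell_toy"`: two 6-protein cells with 3 contact proteins each and
#'   four intercellular edges — the running example.
#' * `"alpha_ladder"`: ten endpoint-disjoint intercellular pairs with equal
#'   scores, so the number of selected bridges equals the coverage target and
#'   grows along the standard alpha grid.
#' * `"lonely_contact"`: a contact protein with no intracellular edge; its
#'   IIS is 0 and its normalized score is the floor.
#' * `"same_symbol"`: the symbol `X` is a contact protein of both cells,
#'   giving an X-X pair; coverage matching must not conflate the two cells'
#'   X.
#'
#' @param name Fixture name.
#' @return List with `net1`, `net2`, `inter` and a `description` string.
#' @export
worked_fixture <- function(name = c("two_cell_toy", "alpha_ladder",
                                    "lonely_contact", "same_symbol")) {
  name <- match.arg(name)
  fx <- switch(
    name,
    two_cell_toy = {
      e1 <- rbind(c("A1", "A4"), c("A4", "A2"), c("A1", "A2"),
                  c("A2", "A5"), c("A3", "A5"), c("A5", "A6"))
      e2 <- rbind(c("B1", "B4"), c("B2", "B4"), c("B2", "B3"),
                  c("B3", "B5"), c("B4", "B6"), c("B5", "B6"))
      list(net1 = cell_network("cell_a", e1, contacts = c("A1", "A2", "A3")),
           net2 = cell_network("cell_b", e2, contacts = c("B1", "B2", "B3")),
           inter = inter_network("cell_a", "cell_b",
                                 rbind(c("A1", "B1"), c("A1", "B2"),
                                       c("A2", "B2"), c("A3", "B3"))),
           description = "two 6-protein cells, 3 contacts each, 4 intercellular edges")
    },
    alpha_ladder = {
      cs1 <- sprintf("C%02d", 1:10)
      cs2 <- sprintf("D%02d", 1:10)
      # every contact hangs off one shared non-contact hub: equal IIS, and
      # the ten intercellular pairs share no endpoints
      e1 <- cbind(cs1, "HUB_A")
      e2 <- cbind(cs2, "HUB_B")
      list(net1 = cell_network("cell_a", e1, contacts = cs1),
           net2 = cell_network("cell_b", e2, contacts = cs2),
           inter = inter_network("cell_a", "cell_b", cbind(cs1, cs2)),
           description = "ten disjoint equal-cost pairs; selection count tracks the coverage target")
    },
    lonely_contact = {
      e1 <- rbind(c("A1", "A3"), c("A3", "A4"))
      e2 <- rbind(c("B1", "B2"), c("B2", "B3"))
      list(net1 = cell_network("cell_a", e1, proteins = c("A1", "A2", "A3", "A4"),
                               contacts = c("A1", "A2")),
           net2 = cell_network("cell_b", e2, contacts = c("B1", "B2")),
           inter = inter_network("cell_a", "cell_b",
                                 rbind(c("A1", "B1"), c("A2", "B2"))),
           description = "contact A2 is intracellularly isolated: raw IIS 0, normalized IIS = floor")
    },
    same_symbol = {
      e1 <- rbind(c("X", "A2"), c("Z", "A2"), c("Y0", "A2"))
      e2 <- rbind(c("X", "B2"), c("Y", "B2"))
      list(net1 = cell_network("cell_a", e1, contacts = c("X", "Z", "Y0")),
           net2 = cell_network("cell_b", e2, contacts = c("X", "Y")),
           inter = inter_network("cell_a", "cell_b",
                                 rbind(c("X", "X"), c("X", "Y"), c("Z", "X"))),
           description = "symbol X is a contact in both cells; matching is cell-respecting")
    })
  fx$name <- name
  fx
}
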