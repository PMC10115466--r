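#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML mapping with the input paths and analysis
#' settings. Recognized keys (defaults in parentheses):
#' `edges1`, `edges2`, `proteome1`, `proteome2`, `lr_pairs` — input paths;
#' `annotation` — optional annotation TSV (`cell`, `protein` columns);
#' `alpha_grid` (0.1, 0.2, 0.4, 0.6, 0.8); `centrality_metric`
#' (`"pagerank"`, or `"betweenness"`); `damping` (0.85); `epsilon` (0.001);
#' `iis_floor` (1e-9); `baseline_repetitions` (10000); `seed` (1);
#' `cell1_label` ("cell1"), `cell2_label` ("cell2"); `output_dir` (".").
#'
#' @param path Path to the YAML file, or a named list already in memory.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(alpha_grid = c(0.1, 0.2, 0.4, 0.6, 0.8),
                   centrality_metric = "pagerank",
                   damping = 0.85, epsilon = 0.001, iis_floor = 1e-9,
                   baseline_repetitions = 10000L, seed = 1L,
                   cell1_label = "cell1", cell2_label = "cell2",
                   output_dir = ".", annotation = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  }
  cfg$alpha_grid <- as.numeric(cfg$alpha_grid)
  if (any(cfg$alpha_grid <= 0) || any(cfg$alpha_grid > 1)) {
    stop("alpha_grid values must lie in (0, 1]")
  }
  if (!cfg$centrality_metric %in% c("pagerank", "betweenness")) {
    stop("centrality_metric must be 'pagerank' or 'betweenness'")
  }
  structure(cfg, class = "run_config")
}

config_inputs <- function(config, keys) {
  for (k in keys) {
    if (is.null(config[[k]])) stop("config is missing required input: ", k)
    if (!file.exists(config[[k]])) stop("input file not found: ", config[[k]])
  }
}

# provenance record: everything needed to re-execute bit-identically.
# Deliberately excludes wall-clock time so identical runs write identical
# bytes.
write_provenance <- function(config, stage, inputs, outputs, extra = list()) {
  rec <- list(stage = stage,
              package_version = as.character(utils::packageVersion("ppibridge")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = config$seed,
              config = unclass(config)[order(names(config))],
              input_md5 = as.list(tools::md5sum(unlist(inputs))),
              outputs = as.list(outputs))
  rec <- c(rec, extra)
  path <- file.path(config$output_dir, paste0("provenance_", stage, ".yaml"))
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Score step: networks in, IIS tables out
#'
#' Reads the two edge lists, restricts them to their proteomes, identifies
#' the contact proteins and the intercellular network from the
#' ligand-receptor table, removes intracellularly unconnected proteins,
#' computes centrality and the intracellular importance scores, and writes
#' per-cell IIS and contributor tables plus the intercellular edge list to
#' the output directory.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @return Invisibly, a list with the in-memory `net1`, `net2`, `inter`,
#'   `iis1`, `iis2` and the written paths.
#' @export
run_score <- function(config) {
  config <- read_run_config(config)
  config_inputs(config, c("edges1", "edges2", "proteome1", "proteome2",
                          "lr_pairs"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  net1 <- read_edge_list(config$edges1, config$cell1_label)
  net2 <- read_edge_list(config$edges2, config$cell2_label)
  net1 <- restrict_to_proteome(net1, read_proteome(config$proteome1))
  net2 <- restrict_to_proteome(net2, read_proteome(config$proteome2))
  ic <- identify_contacts(net1, net2, read_lr_pairs(config$lr_pairs))
  message(sprintf("%s: %d proteins / %d edges; %s: %d proteins / %d edges before pruning",
                  ic$net1$cell_label, length(ic$net1$proteins), nrow(ic$net1$edges),
                  ic$net2$cell_label, length(ic$net2$proteins), nrow(ic$net2$edges)))
  net1 <- remove_unconnected(ic$net1)
  net2 <- remove_unconnected(ic$net2)
  message(sprintf("after removing unconnected proteins: %d and %d proteins",
                  length(net1$proteins), length(net2$proteins)))

  centrality <- switch(config$centrality_metric,
                       pagerank = function(net) {
                         pagerank_centrality(net, damping = config$damping,
                                             epsilon = config$epsilon)
                       },
                       betweenness = betweenness_centrality)
  score_cell <- function(net, inter_side) {
    # contacts dropped by pruning keep a floor score via an explicit 0 entry
    tab <- compute_iis(net, centrality(net))
    lost <- setdiff(inter_side, names(tab$raw))
    if (length(lost) > 0L) {
      tab$raw[lost] <- 0
      tab$contributions[lost] <- list(numeric(0))
    }
    normalize_iis(tab, floor = config$iis_floor)
  }
  iis1 <- score_cell(net1, unique(ic$inter$edges[, 1L]))
  iis2 <- score_cell(net2, unique(ic$inter$edges[, 2L]))

  paths <- c(iis1 = file.path(config$output_dir, "iis_cell1.tsv"),
             iis2 = file.path(config$output_dir, "iis_cell2.tsv"),
             contributors1 = file.path(config$output_dir, "contributors_cell1.tsv"),
             contributors2 = file.path(config$output_dir, "contributors_cell2.tsv"),
             inter = file.path(config$output_dir, "inter_edges.tsv"))
  write_iis_table(iis1, paths[["iis1"]])
  write_iis_table(iis2, paths[["iis2"]])
  write_contributors(iis1, paths[["contributors1"]])
  write_contributors(iis2, paths[["contributors2"]])
  utils::write.table(ic$inter$edges, paths[["inter"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_provenance(config, "score",
                   inputs = config[c("edges1", "edges2", "proteome1",
                                     "proteome2", "lr_pairs")],
                   outputs = paths)
  invisible(list(net1 = net1, net2 = net2, inter = ic$inter,
                 iis1 = iis1, iis2 = iis2, paths = paths))
}

#' Bridge step: IIS tables in, per-alpha bridge selections out
#'
#' Consumes the score step's outputs (re-reading them from the output
#' directory so the two steps can be run in separate sessions), builds the
#' bridge problem, solves it across the alpha grid, ranks all pairs by OIS,
#' and — when an annotation file is configured — compares the selections'
#' annotation rate against the random baseline.
#'
#' @param config A `run_config`.
#' @param score Optional in-memory result of [run_score()]; when omitted the
#'   score step's files in `output_dir` are read.
#' @return Invisibly, a list with `problem`, `sweep`, `ois` and the written
#'   paths.
#' @export
run_bridges <- function(config, score = NULL) {
  config <- read_run_config(config)
  out <- config$output_dir
  if (is.null(score)) {
    iis1 <- read_iis_table(file.path(out, "iis_cell1.tsv"),
                           metric = config$centrality_metric)
    iis2 <- read_iis_table(file.path(out, "iis_cell2.tsv"),
                           metric = config$centrality_metric)
    em <- as.matrix(utils::read.table(file.path(out, "inter_edges.tsv"),
                                      sep = "\t", header = FALSE,
                                      colClasses = "character"))
    inter <- inter_network(config$cell1_label, config$cell2_label, em)
  } else {
    iis1 <- score$iis1; iis2 <- score$iis2; inter <- score$inter
  }
  problem <- bridge_problem(inter, iis1, iis2, alpha = config$alpha_grid[1L])
  sweep <- alpha_sweep(problem, config$alpha_grid)
  ois <- compute_ois(problem)

  paths <- c(report = file.path(out, "bridge_report.tsv"),
             ois = file.path(out, "ois_ranking.tsv"))
  rep_df <- sweep$summary
  rep_df$objective <- format_num(rep_df$objective)
  utils::write.table(rep_df, paths[["report"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ois_out <- ois
  ois_out$pair_score <- format_num(ois_out$pair_score)
  ois_out$ois <- format_num(ois_out$ois)
  utils::write.table(ois_out, paths[["ois"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (i in seq_along(sweep$solutions)) {
    p <- file.path(out, sprintf("bridges_alpha_%s.tsv",
                                gsub("\\.", "p", format(config$alpha_grid[i]))))
    write_solution(problem, sweep$solutions[[i]], p)
    paths[p] <- p
  }

  if (!is.null(config$annotation)) {
    ann_df <- utils::read.table(config$annotation, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = "character")
    annotated <- list(
      cell1 = ann_df$protein[ann_df$cell == config$cell1_label],
      cell2 = ann_df$protein[ann_df$cell == config$cell2_label])
    bl <- baseline_report(problem, sweep, annotated,
                          repetitions = config$baseline_repetitions,
                          seed = config$seed)
    bl$selected_rate <- format_num(bl$selected_rate)
    bl$baseline_mean_rate <- format_num(bl$baseline_mean_rate)
    p <- file.path(out, "baseline_report.tsv")
    utils::write.table(bl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["baseline"] <- p
  }
  for (i in seq_len(nrow(sweep$summary))) {
    message(sprintf("alpha %.2g: %d pair(s) selected covering %d/%d edges (objective %.4g)",
                    sweep$summary$alpha[i], sweep$summary$n_selected[i],
                    sweep$summary$n_covered[i], nrow(problem$pairs),
                    sweep$summary$objective[i]))
  }
  write_provenance(config, "bridges",
                   inputs = list(iis1 = file.path(out, "iis_cell1.tsv"),
                                 iis2 = file.path(out, "iis_cell2.tsv"),
                                 inter = file.path(out, "inter_edges.tsv")),
                   outputs = paths)
  invisible(list(problem = problem, sweep = sweep, ois = ois, paths = paths))
}

#' Simulate step: write synthetic pipeline inputs
#'
#' Generates a synthetic two-cell interactome from a spec (YAML file or
#' [synthetic_spec()] arguments) and writes the pipeline input files plus
#' the planted ground truth.
#'
#' @param spec A [synthetic_spec], or the path of a YAML file whose keys are
#'   [synthetic_spec()] arguments.
#' @param dir Output directory.
#' @return Invisibly, the generated `synthetic_interactome`.
#' @export
run_simulate <- function(spec, dir) {
  if (is.character(spec)) {
    spec <- do.call(synthetic_spec, yaml::read_yaml(spec))
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  sim <- generate_interactome(spec)
  write_synthetic_inputs(sim, dir)
  message(sprintf("wrote synthetic inputs for seed %d to %s", spec$seed, dir))
  invisible(sim)
}

#' Default run configuration for a directory of synthetic inputs
#'
#' Convenience wrapper mapping the file names written by
#' [write_synthetic_inputs()] onto a `run_config`.
#'
#' @param input_dir Directory holding the synthetic input files.
#' @param output_dir Output directory for the score/bridge steps.
#' @param ... Further `run_config` overrides (e.g. `alpha_grid`, `seed`).
#' @return A `run_config`.
#' @export
synthetic_run_config <- function(input_dir, output_dir, ...) {
  read_run_config(c(
    list(edges1 = file.path(input_dir, "edges_cell1.tsv"),
         edges2 = file.path(input_dir, "edges_cell2.tsv"),
         proteome1 = file.path(input_dir, "proteome_cell1.txt"),
         proteome2 = file.path(input_dir, "proteome_cell2.txt"),
         lr_pairs = file.path(input_dir, "lr_pairs.tsv"),
         cell1_label = "cell_a", cell2_label = "cell_b",
         output_dir = output_dir),
    list(...)))
}
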