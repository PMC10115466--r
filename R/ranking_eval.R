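#' Overall importance scores (OIS) for candidate pairs
#'
#' Ranks candidate pairs independently of the optimizer: each pair's OIS is
#' the sum of its max-normalized coverage degree (how many intercellular
#' edges the pair covers) and its max-normalized pair score (the sum of the
#' two endpoints' normalized IIS, i.e. the inverse of the pair cost). Both
#' components lie in (0, 1], so OIS lies in (0, 2].
#'
#' @param problem A [bridge_problem].
#' @return Data frame sorted by `ois` descending (ties lexicographic by
#'   cell-1 then cell-2 protein) with columns `cell1_protein`,
#'   `cell2_protein`, `coverage_degree`, `pair_score`, `ois`.
#' @export
compute_ois <- function(problem) {
  stopifnot(inherits(problem, "bridge_problem"))
  n <- nrow(problem$pairs)
  if (n == 0L) stop("empty bridge problem")
  deg <- rowSums(problem$coverage)
  score <- 1 / problem$cost          # sum of the endpoints' normalized IIS
  ois <- deg / max(deg) + score / max(score)
  df <- data.frame(cell1_protein = problem$pairs[, 1L],
                   cell2_protein = problem$pairs[, 2L],
                   coverage_degree = as.integer(deg),
                   pair_score = score,
                   ois = ois,
                   stringsAsFactors = FALSE)
  df[order(-df$ois, df$cell1_protein, df$cell2_protein), , drop = FALSE]
}

# distinct cell-tagged proteins appearing in the given pairs (rows of the
# problem's pair matrix); returns "1:<id>" / "2:<id>" tags
tagged_proteins <- function(pairs) {
  unique(c(paste0("1:", pairs[, 1L]), paste0("2:", pairs[, 2L])))
}

tag_annotated <- function(annotated) {
  c(paste0("1:", annotated$cell1), paste0("2:", annotated$cell2))
}

#' Annotation rate of the proteins in a bridge selection
#'
#' Fraction of the distinct cell-tagged proteins occurring in the selected
#' pairs that carry the annotation (e.g. known disease association). A
#' protein appearing in several selected pairs counts once; the same symbol
#' in the two cells counts as two distinct proteins.
#'
#' @param solution A `bridge_solution` with at least one selected pair.
#' @param annotated List with character vectors `cell1` and `cell2` naming
#'   the annotated proteins of each cell.
#' @return The annotation rate in \[0, 1\].
#' @export
association_rate <- function(solution, annotated) {
  stopifnot(inherits(solution, "bridge_solution"))
  if (length(solution$selected) == 0L) {
    stop("association rate undefined for an empty selection")
  }
  prot <- tagged_proteins(solution$pairs)
  mean(prot %in% tag_annotated(annotated))
}

#' Random-selection baseline for the annotation rate
#'
#' Repeatedly draws as many candidate pairs, uniformly without replacement,
#' as the optimizer selected, and computes the annotation rate of the drawn
#' pairs' distinct proteins — the null expectation against which the
#' optimizer's [association_rate()] is compared.
#'
#' @param problem A [bridge_problem].
#' @param n_pairs Number of pairs drawn per repetition (at most the number
#'   of candidate pairs).
#' @param annotated List with vectors `cell1`, `cell2` of annotated proteins.
#' @param repetitions Number of random draws.
#' @param seed Optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return List with `mean_rate`, `sd_rate`, `repetitions`, `n_pairs` and
#'   `rates` (the per-repetition rates).
#' @export
random_baseline <- function(problem, n_pairs, annotated,
                            repetitions = 10000L, seed = NULL) {
  stopifnot(inherits(problem, "bridge_problem"), repetitions >= 1L)
  n <- nrow(problem$pairs)
  if (n_pairs > n) stop("cannot draw ", n_pairs, " pairs from ", n)
  if (n_pairs < 1L) stop("n_pairs must be at least 1")
  ann <- tag_annotated(annotated)
  tags1 <- paste0("1:", problem$pairs[, 1L])
  tags2 <- paste0("2:", problem$pairs[, 2L])
  draw_rate <- function() {
    sel <- sample.int(n, n_pairs)
    prot <- unique(c(tags1[sel], tags2[sel]))
    mean(prot %in% ann)
  }
  rates <- with_rng_seed(seed, vapply(seq_len(repetitions), function(r) draw_rate(),
                                      numeric(1)))
  list(mean_rate = mean(rates),
       sd_rate = stats::sd(rates),
       repetitions = as.integer(repetitions),
       n_pairs = as.integer(n_pairs),
       rates = rates)
}

#' Exact expectation of the random-baseline rate by enumeration
#'
#' Averages the annotation rate over every possible draw of `n_pairs`
#' candidate pairs. Feasible only for small instances; used as the
#' independent check on [random_baseline()]'s Monte-Carlo mean.
#'
#' @inheritParams random_baseline
#' @return List with `mean_rate` and `sd_rate` over all draws.
#' @export
baseline_expectation <- function(problem, n_pairs, annotated) {
  stopifnot(inherits(problem, "bridge_problem"))
  n <- nrow(problem$pairs)
  if (n_pairs > n) stop("cannot draw ", n_pairs, " pairs from ", n)
  if (choose(n, n_pairs) > 1e6) stop("instance too large for enumeration")
  ann <- tag_annotated(annotated)
  tags1 <- paste0("1:", problem$pairs[, 1L])
  tags2 <- paste0("2:", problem$pairs[, 2L])
  combos <- utils::combn(n, n_pairs)
  rates <- apply(combos, 2L, function(sel) {
    prot <- unique(c(tags1[sel], tags2[sel]))
    mean(prot %in% ann)
  })
  list(mean_rate = mean(rates), sd_rate = stats::sd(rates))
}

#' Compare the optimizer's annotation rate with the random baseline
#'
#' Runs the optimizer-vs-random comparison across an alpha grid: for each
#' alpha, the annotation rate of the optimizer's selection and the mean rate
#' of random selections of the same size.
#'
#' @param problem A [bridge_problem].
#' @param sweep Result of [alpha_sweep()] on the problem.
#' @param annotated List with vectors `cell1`, `cell2` of annotated proteins.
#' @param repetitions Random draws per alpha.
#' @param seed Optional integer seed.
#' @return Data frame with one row per alpha: `alpha`, `n_selected`,
#'   `selected_rate`, `baseline_mean_rate`, `repetitions`.
#' @export
baseline_report <- function(problem, sweep, annotated,
                            repetitions = 10000L, seed = NULL) {
  rows <- lapply(seq_along(sweep$solutions), function(i) {
    sol <- sweep$solutions[[i]]
    bl <- random_baseline(problem, length(sol$selected), annotated,
                          repetitions = repetitions,
                          seed = if (is.null(seed)) NULL else seed + i)
    data.frame(alpha = sol$alpha,
               n_selected = length(sol$selected),
               selected_rate = association_rate(sol, annotated),
               baseline_mean_rate = bl$mean_rate,
               repetitions = as.integer(repetitions))
  })
  do.call(rbind, rows)
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
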