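#' Pair costs from normalized importance scores
#'
#' The cost of candidate pair i = (u, v) is the inverse of the sum of the
#' endpoints' normalized IIS, `s_i = 1 / (IIS1(u) + IIS2(v))`: pairs joining
#' two intracellularly important contact proteins are cheap to select. The
#' normalization floor guarantees every cost is finite and positive.
#'
#' @param inter An [inter_network].
#' @param iis1,iis2 Normalized `iis_table`s for cell 1 and cell 2.
#' @return Numeric vector of costs, one per intercellular edge, in the
#'   network's canonical pair order.
#' @export
pair_costs <- function(inter, iis1, iis2) {
  stopifnot(inherits(inter, "inter_network"),
            inherits(iis1, "iis_table"), inherits(iis2, "iis_table"))
  if (is.null(iis1$normalized) || is.null(iis2$normalized)) {
    stop("normalized IIS required; call normalize_iis() first")
  }
  u <- inter$edges[, 1L]
  v <- inter$edges[, 2L]
  miss1 <- setdiff(u, names(iis1$normalized))
  miss2 <- setdiff(v, names(iis2$normalized))
  if (length(miss1) + length(miss2) > 0L) {
    stop("missing normalized IIS for intercellular endpoints: ",
         paste(utils::head(c(miss1, miss2), 5L), collapse = ", "))
  }
  s <- 1 / (unname(iis1$normalized[u]) + unname(iis2$normalized[v]))
  stopifnot(all(is.finite(s)), all(s > 0))
  s
}

#' Coverage relation between candidate pairs and intercellular edges
#'
#' Pair i = (u, v) covers interaction j = (a, b) iff they share an endpoint
#' on the same cell side: `u == a` or `v == b`. Matching is cell-respecting —
#' a symbol present in both cells never matches across sides. Every pair
#' covers its own interaction.
#'
#' @param inter An [inter_network].
#' @return Logical matrix `c` with `c[i, j]` = pair i covers edge j.
#' @export
coverage_relation <- function(inter) {
  stopifnot(inherits(inter, "inter_network"))
  u <- inter$edges[, 1L]
  v <- inter$edges[, 2L]
  outer(u, u, "==") | outer(v, v, "==")
}

#' Assemble a bridge selection problem
#'
#' Bundles the candidate pair set P (= the intercellular edge set E), the
#' pair costs s, the pair-edge coverage relation c, and the minimum coverage
#' fraction alpha into one optimization instance:
#' minimize `sum_i x_i s_i` subject to `x_i c_ij <= y_j`,
#' `sum_j y_j >= ceil(alpha |E|)`, `y_j <= sum_i x_i c_ij`, with binary x, y.
#'
#' @param inter An [inter_network].
#' @param iis1,iis2 Normalized `iis_table`s (see [normalize_iis()]).
#' @param alpha Minimum coverage fraction in (0, 1].
#' @param cost Optional precomputed cost vector (defaults to
#'   [pair_costs()]); useful for synthetic instances.
#' @return Object of class `bridge_problem` with fields `pairs` (two-column
#'   character matrix), `cost`, `coverage`, `alpha`, `cell1_label`,
#'   `cell2_label`.
#' @export
bridge_problem <- function(inter, iis1 = NULL, iis2 = NULL, alpha = 0.1,
                           cost = NULL) {
  stopifnot(inherits(inter, "inter_network"), alpha > 0, alpha <= 1)
  if (nrow(inter$edges) == 0L) stop("no candidate pairs: empty intercellular network")
  if (is.null(cost)) cost <- pair_costs(inter, iis1, iis2)
  stopifnot(length(cost) == nrow(inter$edges), all(cost > 0))
  structure(list(pairs = inter$edges,
                 cost = as.numeric(cost),
                 coverage = coverage_relation(inter),
                 alpha = alpha,
                 cell1_label = inter$cell1_label,
                 cell2_label = inter$cell2_label),
            class = "bridge_problem")
}

#' @export
print.bridge_problem <- function(x, ...) {
  cat(sprintf("bridge_problem %s--%s: %d candidate pairs, alpha = %g\n",
              x$cell1_label, x$cell2_label, nrow(x$pairs), x$alpha))
  invisible(x)
}

# integer coverage requirement; the 1e-9 slack guards against binary-float
# overshoot (0.1 * 30 = 3.0000000000000004 must require 3 edges, not 4)
coverage_target <- function(alpha, n_edges) {
  as.integer(ceiling(alpha * n_edges - 1e-9))
}

# ordering used for all tie-breaks: feasible solutions are compared by
# (cost, number of pairs, lexicographic rank of the sorted index set);
# costs within `tol` are treated as equal
better_solution <- function(cost_a, sel_a, cost_b, sel_b, tol = 1e-9) {
  if (cost_a < cost_b - tol) return(TRUE)
  if (cost_a > cost_b + tol) return(FALSE)
  if (length(sel_a) != length(sel_b)) return(length(sel_a) < length(sel_b))
  d <- which(sel_a != sel_b)
  if (length(d) == 0L) return(FALSE)
  sel_a[d[1L]] < sel_b[d[1L]]
}

new_bridge_solution <- function(problem, selected, alpha, status) {
  n <- nrow(problem$pairs)
  covered <- if (length(selected) > 0L) {
    colSums(problem$coverage[selected, , drop = FALSE]) > 0L
  } else {
    rep(FALSE, n)
  }
  structure(list(selected = sort(selected),
                 covered = which(covered),
                 objective = sum(problem$cost[selected]),
                 alpha = alpha,
                 n_pairs = n,
                 coverage_target = coverage_target(alpha, n),
                 pairs = problem$pairs[sort(selected), , drop = FALSE],
                 status = status),
            class = "bridge_solution")
}

#' @export
print.bridge_solution <- function(x, ...) {
  cat(sprintf(
    "bridge_solution (alpha = %g): %d pair(s) selected, %d/%d edges covered, objective %.6g [%s]\n",
    x$alpha, length(x$selected), length(x$covered), x$n_pairs, x$objective,
    x$status))
  invisible(x)
}

#' Solve the bridge selection problem exactly
#'
#' Branch-and-bound search over pair inclusion. Only the pair variables x are
#' branched on; the edge-coverage variables y are implied (an edge is covered
#' iff a selected pair covers it) and reconstructed for the returned
#' solution, which therefore satisfies the full model including the linking
#' constraints. Bounding: a partial selection is pruned when its cost plus
#' the sum of the cheapest m remaining costs exceeds the incumbent, where m
#' is the least number of additional pairs that could supply the missing
#' coverage, and when the remaining pairs cannot reach the coverage target
#' at all.
#'
#' Alternative optima are resolved deterministically: among all selections
#' whose cost is within `1e-9` of the optimum, the one with fewest pairs and
#' then lexicographically smallest sorted index set is returned, so output is
#' reproducible across platforms and independent of search order.
#'
#' @param problem A [bridge_problem].
#' @param alpha Coverage fraction; defaults to the problem's.
#' @return A `bridge_solution` with fields `selected` (pair indices),
#'   `pairs`, `covered` (edge indices), `objective`, `status`.
#' @export
solve_bridges <- function(problem, alpha = problem$alpha) {
  stopifnot(inherits(problem, "bridge_problem"), alpha > 0, alpha <= 1)
  n <- nrow(problem$pairs)
  K <- coverage_target(alpha, n)
  cov <- problem$coverage
  cost <- problem$cost
  tol <- 1e-9

  if (K == 0L) return(new_bridge_solution(problem, integer(0), alpha, "optimal"))

  # explore pairs in descending coverage-per-cost appeal; index order breaks
  # ties so the lexicographic incumbent is found early
  gain <- rowSums(cov)
  explore <- order(-(gain / cost), seq_len(n))
  # suffix[k]: union coverage achievable by pairs explore[k..n]
  suffix_cover <- matrix(FALSE, n + 1L, n)
  for (k in n:1) {
    suffix_cover[k, ] <- suffix_cover[k + 1L, ] | cov[explore[k], ]
  }
  # cumulative gains/costs along the ratio-sorted order drive a fractional
  # covering bound: marginal gains never exceed the static gain, so filling
  # the missing coverage fractionally from the best-ratio suffix pairs is a
  # valid lower bound on the completion cost
  gx <- gain[explore]
  cx <- cost[explore]
  cumg <- c(0, cumsum(gx))
  cumc <- c(0, cumsum(cx))
  frac_bound <- function(k, missing) {
    avail <- cumg[n + 1L] - cumg[k]
    if (avail < missing) return(Inf)
    target <- missing + cumg[k]
    t <- findInterval(target - 1e-9, cumg) + 1L  # first t+1 with cumg >= target
    full <- cumc[t - 1L] - cumc[k]
    part <- (target - cumg[t - 1L]) * cx[t - 1L] / gx[t - 1L]
    full + part
  }

  best <- list(cost = Inf, sel = integer(0))

  rec <- function(k, selected, covered, acc_cost) {
    ncov <- sum(covered)
    if (ncov >= K) {
      sel <- sort(selected)
      if (is.infinite(best$cost) ||
          better_solution(acc_cost, sel, best$cost, best$sel, tol)) {
        best <<- list(cost = acc_cost, sel = sel)
      }
      return(invisible(NULL))
    }
    if (k > n) return(invisible(NULL))
    # reachability: can the remaining pairs still supply K covered edges?
    if (sum(covered | suffix_cover[k, ]) < K) return(invisible(NULL))
    if (acc_cost + frac_bound(k, K - ncov) > best$cost + tol) {
      return(invisible(NULL))
    }
    i <- explore[k]
    rec(k + 1L, c(selected, i), covered | cov[i, ], acc_cost + cost[i])
    rec(k + 1L, selected, covered, acc_cost)
    invisible(NULL)
  }
  rec(1L, integer(0), rep(FALSE, n), 0)

  if (is.infinite(best$cost)) {
    stop("bridge problem infeasible")  # unreachable for alpha <= 1
  }
  new_bridge_solution(problem, best$sel, alpha, "optimal")
}

#' Exhaustive-enumeration oracle for the bridge problem
#'
#' Enumerates all 2^|P| pair subsets and returns the minimum-cost subset
#' covering at least `ceil(alpha |E|)` edges, with ties broken by fewer
#' pairs, then lexicographic pair order — the same tie-break as
#' [solve_bridges()], against which it serves as an independent correctness
#' oracle. Guarded to |P| <= 20.
#'
#' @param problem A [bridge_problem].
#' @param alpha Coverage fraction; defaults to the problem's.
#' @return A `bridge_solution` with `status = "optimal-exhaustive"`.
#' @export
brute_force_bridges <- function(problem, alpha = problem$alpha) {
  stopifnot(inherits(problem, "bridge_problem"), alpha > 0, alpha <= 1)
  n <- nrow(problem$pairs)
  if (n > 20L) stop("brute-force oracle guarded to at most 20 pairs, got ", n)
  K <- coverage_target(alpha, n)
  cost <- problem$cost
  # per-pair coverage bitmask over the n edges (n <= 20 fits in an integer)
  mask <- vapply(seq_len(n), function(i) {
    sum(2^(which(problem$coverage[i, ]) - 1L))
  }, numeric(1))
  n_sub <- 2^n
  covmask <- numeric(n_sub)   # doubles hold exact integers < 2^21
  subcost <- numeric(n_sub)
  size <- integer(n_sub)
  popcount <- function(x) {
    cnt <- integer(length(x))
    while (any(x > 0)) {
      cnt <- cnt + as.integer(x %% 2)
      x <- x %/% 2
    }
    cnt
  }
  for (b in seq_len(n)) {          # subset DP over the lowest unset bit
    bit <- 2^(b - 1L)
    lo <- seq_len(bit)             # subsets with bits only below b
    idx <- lo + bit
    covmask[idx] <- bitwOr(as.integer(covmask[lo]), as.integer(mask[b]))
    subcost[idx] <- subcost[lo] + cost[b]
    size[idx] <- size[lo] + 1L
  }
  feasible <- which(popcount(covmask) >= K)
  if (length(feasible) == 0L) stop("bridge problem infeasible")
  zmin <- min(subcost[feasible])
  cand <- feasible[subcost[feasible] <= zmin + 1e-9]
  cand <- cand[size[cand] == min(size[cand])]
  sels <- lapply(cand - 1L, function(s) which(bitwAnd(s, 2^(seq_len(n) - 1L)) > 0))
  pick <- 1L
  for (ii in seq_along(sels)[-1L]) {
    if (better_solution(subcost[cand[ii]], sels[[ii]],
                        subcost[cand[pick]], sels[[pick]])) {
      pick <- ii
    }
  }
  new_bridge_solution(problem, sels[[pick]], alpha, "optimal-exhaustive")
}

#' Solve the bridge problem across a grid of coverage fractions
#'
#' @param problem A [bridge_problem].
#' @param alphas Ascending or arbitrary coverage fractions in (0, 1];
#'   defaults to the standard prioritization grid 0.1-0.8.
#' @return List with `solutions` (one `bridge_solution` per alpha, named by
#'   alpha) and `summary`, a data frame with one row per alpha: `alpha`,
#'   `n_selected`, `n_covered`, `coverage_target`, `objective`.
#' @export
alpha_sweep <- function(problem, alphas = c(0.1, 0.2, 0.4, 0.6, 0.8)) {
  stopifnot(all(alphas > 0), all(alphas <= 1))
  solutions <- lapply(alphas, function(a) solve_bridges(problem, a))
  names(solutions) <- format(alphas)
  summary <- data.frame(
    alpha = alphas,
    n_selected = vapply(solutions, function(s) length(s$selected), integer(1)),
    n_covered = vapply(solutions, function(s) length(s$covered), integer(1)),
    coverage_target = vapply(solutions, function(s) s$coverage_target, integer(1)),
    objective = vapply(solutions, function(s) s$objective, numeric(1)),
    row.names = NULL)
  list(solutions = solutions, summary = summary)
}

#' Export one solution of an alpha sweep as TSV
#'
#' Columns: `alpha`, `cell1_protein`, `cell2_protein`, `s_i`,
#' `coverage_degree`, `selected` — one row per candidate pair.
#'
#' @param problem The [bridge_problem] the solution was computed on.
#' @param solution A `bridge_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(problem, solution, path) {
  stopifnot(inherits(problem, "bridge_problem"),
            inherits(solution, "bridge_solution"))
  df <- data.frame(alpha = format_num(solution$alpha),
                   cell1_protein = problem$pairs[, 1L],
                   cell2_protein = problem$pairs[, 2L],
                   s_i = format_num(problem$cost),
                   coverage_degree = rowSums(problem$coverage),
                   selected = as.integer(seq_len(nrow(problem$pairs)) %in%
                                           solution$selected),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
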