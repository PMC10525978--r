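#' Truncation candidate selection on a selection criterion
#'
#' Keeps the top `ceiling(frac * n_sex)` individuals of each sex ranked by
#' the criterion, ties broken by ascending individual id (deterministic).
#'
#' @param pop a `Population`.
#' @param score numeric criterion (e.g. WSG or a single-trait GEBV), one
#'   value per member of `pop`.
#' @param male_frac,female_frac selected fraction per sex.
#' @return list with member-index vectors `males` and `females`.
#' @export
select_candidates_by_score <- function(pop, score, male_frac = 0.10,
                                       female_frac = 0.50) {
  stopifnot(length(score) == n_ind(pop))
  pick <- function(idx, frac) {
    if (length(idx) == 0) stop("selection error: empty sex class")
    k <- ceiling(frac * length(idx))
    if (k < 1) stop("selection error: empty candidate set")
    idx[order(-score[idx], pop$id[idx])][seq_len(k)]
  }
  list(males = pick(which(pop$sex == "M"), male_frac),
       females = pick(which(pop$sex == "F"), female_frac))
}

#' Expected progeny selection index
#'
#' `I_ij = WSG_ij - gamma * f_ij * sd_wsg`, where `WSG_ij` is the
#' midparent WSG `(wsg_i + wsg_j) / 2`, `f_ij` the expected progeny
#' inbreeding (the parents' genomic kinship), `gamma` the inbreeding
#' effect on the index and `sd_wsg` the standard deviation of candidate
#' WSG (the index scale).
#'
#' @param wsg_i,wsg_j parental WSG values (vectorized).
#' @param f_ij expected progeny inbreeding of the mating.
#' @param gamma inbreeding-effect coefficient, `>= 0`.
#' @param sd_wsg standard deviation of WSG over all candidates.
#' @return expected progeny index value(s).
#' @export
expected_progeny_index <- function(wsg_i, wsg_j, f_ij, gamma, sd_wsg) {
  if (gamma < 0 || sd_wsg < 0) stop("gamma and sd_wsg must be non-negative")
  (wsg_i + wsg_j) / 2 - gamma * f_ij * sd_wsg
}

#' Selection-index matrix over a candidate grid
#'
#' @param wsg_m,wsg_f WSG of male and female candidates.
#' @param F_mat male x female matrix of expected progeny inbreeding
#'   (parental genomic kinship).
#' @param gamma inbreeding-effect coefficient.
#' @param sd_wsg candidate WSG standard deviation.
#' @return male x female matrix of `I_ij`.
#' @export
selection_index_matrix <- function(wsg_m, wsg_f, F_mat, gamma, sd_wsg) {
  stopifnot(nrow(F_mat) == length(wsg_m), ncol(F_mat) == length(wsg_f))
  outer(wsg_m, wsg_f, `+`) / 2 - gamma * F_mat * sd_wsg
}

#' Optimal mate allocation (transportation LP)
#'
#' Maximizes `sum I_ij x_ij` over binary `x` subject to row sums
#' `<= male_cap`, column sums `<= female_cap` and
#' `sum x_ij = required_matings`. The constraint matrix is a
#' transportation polytope, so the LP optimum is integral; it is computed
#' exactly by successive-shortest-path min-cost flow.
#'
#' @param I male x female matrix of selection-index values.
#' @param male_cap maximum matings per male (default 10).
#' @param female_cap maximum matings per female (default 1).
#' @param required_matings total number of matings; defaults to
#'   `min(a * male_cap, b * female_cap)`.
#' @return list with binary matrix `x`, `objective`, and `pairs`
#'   (data.frame of selected `sire_row`, `dam_col`, `index`).
#' @export
solve_mating_lp <- function(I, male_cap = 10, female_cap = 1,
                            required_matings = NULL) {
  a <- nrow(I); b <- ncol(I)
  if (a < 1 || b < 1) stop("empty candidate grid")
  cap_total <- min(a * male_cap, b * female_cap)
  if (is.null(required_matings)) required_matings <- cap_total
  if (required_matings > cap_total)
    stop("infeasible: required_matings exceeds capacity")
  flow <- mcmf_transport(-I, male_cap, female_cap, required_matings)
  x <- flow$x
  pairs <- which(x > 0, arr.ind = TRUE)
  pairs <- data.frame(sire_row = pairs[, 1], dam_col = pairs[, 2],
                      index = I[pairs])
  pairs <- pairs[order(-pairs$index), , drop = FALSE]
  rownames(pairs) <- NULL
  list(x = x, objective = sum(I * x), pairs = pairs)
}

# Min-cost flow on the bipartite transportation graph by successive
# shortest paths (Bellman-Ford, handles negative costs). Node layout:
# 1 = source, 2..(a+1) males, (a+2)..(a+b+1) females, a+b+2 = sink.
mcmf_transport <- function(cost_mat, male_cap, female_cap, required) {
  a <- nrow(cost_mat); b <- ncol(cost_mat)
  s <- 1L; t <- a + b + 2L; n_nodes <- t
  # forward arcs followed by their residual twins (offset n_arc)
  from <- c(rep(s, a), rep(2L:(a + 1L), each = b), (a + 2L):(a + b + 1L))
  to <- c(2L:(a + 1L), rep((a + 2L):(a + b + 1L), times = a), rep(t, b))
  cost <- c(rep(0, a), as.vector(t(cost_mat)), rep(0, b))
  cap <- c(rep(male_cap, a), rep(1L, a * b), rep(female_cap, b))
  n_arc <- length(from)
  from <- c(from, to); to <- c(to, from[seq_len(n_arc)])
  cost <- c(cost, -cost); cap <- c(cap, rep(0L, n_arc))
  flow <- rep(0L, 2L * n_arc)
  twin <- c(n_arc + seq_len(n_arc), seq_len(n_arc))

  pushed <- 0L
  while (pushed < required) {
    # Bellman-Ford over the residual graph
    dist <- rep(Inf, n_nodes); dist[s] <- 0
    prev_arc <- rep(NA_integer_, n_nodes)
    repeat {
      act <- which(cap - flow > 0L & is.finite(dist[from]))
      if (!length(act)) break
      nd <- dist[from[act]] + cost[act]
      improved <- FALSE
      sp <- split(seq_along(act), to[act])
      for (nm in names(sp)) {
        v <- as.integer(nm); ix <- sp[[nm]]
        j <- ix[which.min(nd[ix])]
        if (nd[j] < dist[v] - 1e-12) {
          dist[v] <- nd[j]; prev_arc[v] <- act[j]; improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (!is.finite(dist[t])) stop("infeasible: cannot route required matings")
    # trace path, find bottleneck
    path <- integer(0); v <- t
    while (v != s) { e <- prev_arc[v]; path <- c(path, e); v <- from[e] }
    push <- min(cap[path] - flow[path], required - pushed)
    flow[path] <- flow[path] + push
    flow[twin[path]] <- flow[twin[path]] - push
    pushed <- pushed + push
  }
  x <- matrix(as.numeric(flow[a + seq_len(a * b)]), nrow = a, byrow = TRUE)
  list(x = x, cost = sum(cost_mat * x))
}

#' Realize an LP assignment as a mating plan
#'
#' Distributes `n_offspring` as evenly as possible over the selected
#' pairs; the remainder goes to the pairs with the highest index values.
#'
#' @param sol an [solve_mating_lp()] solution.
#' @param n_offspring total offspring to produce.
#' @param sire_ids,dam_ids candidate ids indexing the rows / columns of
#'   the solved grid.
#' @return `MatingPlan` data.frame with columns `sire`, `dam`,
#'   `n_offspring`, `index`.
#' @export
realize_lp_plan <- function(sol, n_offspring, sire_ids, dam_ids) {
  pairs <- sol$pairs
  if (nrow(pairs) == 0) stop("plan error: no matings in solution")
  k <- nrow(pairs)
  counts <- rep(n_offspring %/% k, k)
  rem <- n_offspring %% k
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L  # pairs sorted by index
  plan <- data.frame(sire = sire_ids[pairs$sire_row],
                     dam = dam_ids[pairs$dam_col],
                     n_offspring = counts, index = pairs$index)
  plan[plan$n_offspring > 0, , drop = FALSE]
}
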