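# Primal active-set solver for
#   min 1/2 c'Hc - h'c   s.t.  A c = b,  c >= 0
# starting from a feasible point. H need only be positive semi-definite on
# the null space of A (the IIS kinship matrix is, since sum(c) is fixed).
qp_eq_nonneg <- function(H, h, A, b, c0, tol = 1e-10, max_iter = 500L) {
  n <- length(h)
  x <- c0
  active <- x <= tol
  lambda <- rep(0, nrow(A))
  for (iter in seq_len(max_iter)) {
    f <- which(!active)
    nf <- length(f)
    # ridge only the Hessian block so the equality constraints are not
    # perturbed even when the linear term is large
    eps <- 1e-10 * max(1, max(abs(H)))
    M <- rbind(cbind(H[f, f, drop = FALSE] + diag(eps, nf),
                     t(A[, f, drop = FALSE])),
               cbind(A[, f, drop = FALSE], matrix(0, nrow(A), nrow(A))))
    rhs <- c(h[f], b)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol))
      sol <- qr.solve(M + diag(1e-9, nrow(M)), rhs)
    xt <- numeric(n); xt[f] <- sol[seq_len(nf)]
    lambda <- sol[nf + seq_len(nrow(A))]
    p <- xt - x
    if (max(abs(p)) < 1e-9) {
      # at the working-set optimum; check bound multipliers. The KKT
      # system solves H x + A' l = h, so stationarity gives
      # mu = H x - h + A' l on the active bounds.
      mu <- as.vector(H %*% x - h + t(A) %*% lambda)
      w <- which(active)
      if (!length(w) || all(mu[w] >= -1e-7)) return(list(c = x, lambda = lambda))
      active[w[which.min(mu[w])]] <- FALSE
      next
    }
    dec <- f[p[f] < -1e-14]
    alpha <- 1
    blocking <- NA_integer_
    if (length(dec)) {
      ratio <- -x[dec] / p[dec]
      jm <- which.min(ratio)
      if (ratio[jm] < 1) { alpha <- max(ratio[jm], 0); blocking <- dec[jm] }
    }
    x <- x + alpha * p
    x[x < 0] <- 0
    if (!is.na(blocking)) { x[blocking] <- 0; active[blocking] <- TRUE }
  }
  warning("OCS active-set solver hit the iteration cap")
  list(c = x, lambda = lambda)
}

sex_constraints <- function(sex) {
  A <- rbind(as.numeric(sex == "M"), as.numeric(sex == "F"))
  list(A = A, b = c(0.5, 0.5))
}

uniform_contributions <- function(sex) {
  c0 <- numeric(length(sex))
  c0[sex == "M"] <- 0.5 / sum(sex == "M")
  c0[sex == "F"] <- 0.5 / sum(sex == "F")
  c0
}

# max-gain vertex: all weight on the best candidate of each sex
vertex_contributions <- function(g, sex) {
  c0 <- numeric(length(g))
  m <- which(sex == "M"); f <- which(sex == "F")
  c0[m[which.max(g[m])]] <- 0.5
  c0[f[which.max(g[f])]] <- 0.5
  c0
}

#' Preselect male OCS candidates
#'
#' Top `frac` of males ranked by single-trait GEBV (ties broken by id);
#' all females remain candidates for the optimizer.
#'
#' @param pop a `Population`.
#' @param gebv numeric GEBV vector over `pop` members.
#' @param frac selected male fraction (default 0.10).
#' @return list with member-index vectors `males` (preselected) and
#'   `females` (all females).
#' @export
select_ocs_male_candidates <- function(pop, gebv, frac = 0.10) {
  males <- which(pop$sex == "M")
  if (!length(males)) stop("selection error: no males")
  k <- max(1L, ceiling(frac * length(males)))
  list(males = males[order(-gebv[males], pop$id[males])][seq_len(k)],
       females = which(pop$sex == "F"))
}

#' Solve an optimal-contribution-selection problem
#'
#' Contributions `c >= 0` satisfy the sex sums (males total 0.5, females
#' total 0.5). Two formulations:
#' \describe{
#'   \item{maxBVE}{maximize `c'g` subject to offspring mean kinship
#'     `c'Kc <= kinship_upper_bound`; solved by bisecting the penalty
#'     multiplier of the quadratic constraint, each sub-problem a convex
#'     QP.}
#'   \item{minKin}{minimize `c'Kc` subject to the gain constraint
#'     `c'g - gain_baseline >= gain_lower_bound`; the gain constraint is
#'     first checked inactive, else imposed as an equality.}
#' }
#'
#' @param g GEBV vector of the candidates.
#' @param K candidate kinship matrix (IIS genomic kinship).
#' @param sex character vector `"M"` / `"F"` per candidate.
#' @param mode `"maxBVE"` or `"minKin"`.
#' @param kinship_upper_bound bound on `c'Kc` (maxBVE mode).
#' @param gain_lower_bound required gain over `gain_baseline` (minKin).
#' @param gain_baseline reference mean GEBV the gain is measured against
#'   (typically the current population mean).
#' @return list with `c` (contributions), `gain` (`c'g - gain_baseline`),
#'   `kinship` (`c'Kc`), `mode`, and `status`.
#' @export
solve_ocs <- function(g, K, sex, mode = c("maxBVE", "minKin"),
                      kinship_upper_bound = NULL, gain_lower_bound = NULL,
                      gain_baseline = 0) {
  mode <- match.arg(mode)
  stopifnot(length(g) == length(sex), nrow(K) == length(g))
  if (!any(sex == "M") || !any(sex == "F"))
    stop("both sexes must be represented among candidates")
  K <- (K + t(K)) / 2 + diag(1e-8, nrow(K))
  sc <- sex_constraints(sex)
  c_unif <- uniform_contributions(sex)
  qKq <- function(c) as.numeric(t(c) %*% K %*% c)

  if (mode == "minKin") {
    if (is.null(gain_lower_bound)) stop("minKin mode needs gain_lower_bound")
    sol <- qp_eq_nonneg(2 * K, numeric(length(g)), sc$A, sc$b, c_unif)
    gain <- sum(sol$c * g) - gain_baseline
    if (gain >= gain_lower_bound - 1e-9) {
      return(list(c = sol$c, gain = gain, kinship = qKq(sol$c),
                  mode = mode, status = "optimal (gain bound inactive)"))
    }
    c_vx <- vertex_contributions(g, sex)
    gain_max <- sum(c_vx * g) - gain_baseline
    if (gain_max < gain_lower_bound - 1e-9)
      stop("infeasible: gain_lower_bound (", gain_lower_bound,
           ") exceeds maximum achievable gain (", round(gain_max, 6), ")")
    # feasible start on the gain-equality plane
    theta <- (gain_lower_bound - gain) / (gain_max - gain)
    c0 <- (1 - theta) * sol$c + theta * c_vx
    A <- rbind(sc$A, g)
    b <- c(sc$b, gain_baseline + gain_lower_bound)
    sol2 <- qp_eq_nonneg(2 * K, numeric(length(g)), A, b, c0)
    return(list(c = sol2$c, gain = sum(sol2$c * g) - gain_baseline,
                kinship = qKq(sol2$c), mode = mode, status = "optimal"))
  }

  if (is.null(kinship_upper_bound)) stop("maxBVE mode needs kinship_upper_bound")
  # penalty sub-problem min mu c'Kc - g'c, solved in the equivalent scaling
  # min c'Kc - (g/mu)'c so the Hessian stays well-conditioned for small mu
  solve_pen <- function(mu, c0) qp_eq_nonneg(2 * K, g / mu, sc$A, sc$b, c0)$c
  # penalty bisection: c'Kc is non-increasing in mu
  mu_lo <- 1e-6
  c_lo <- solve_pen(mu_lo, vertex_contributions(g, sex))
  if (qKq(c_lo) <= kinship_upper_bound + 1e-9) {
    return(list(c = c_lo, gain = sum(c_lo * g) - gain_baseline,
                kinship = qKq(c_lo), mode = mode,
                status = "optimal (kinship bound inactive)"))
  }
  mu_hi <- 1
  c_hi <- solve_pen(mu_hi, c_unif)
  while (qKq(c_hi) > kinship_upper_bound && mu_hi < 1e8) {
    mu_hi <- mu_hi * 10
    c_hi <- solve_pen(mu_hi, c_hi)
  }
  if (qKq(c_hi) > kinship_upper_bound + 1e-9)
    stop("infeasible: kinship_upper_bound (", kinship_upper_bound,
         ") below minimum achievable offspring kinship (",
         round(qKq(c_hi), 6), ")")
  c_cur <- c_hi
  for (it in 1:60) {
    mu <- sqrt(mu_lo * mu_hi)
    c_cur <- solve_pen(mu, c_cur)
    if (qKq(c_cur) > kinship_upper_bound) mu_lo <- mu else mu_hi <- mu
    if (mu_hi / mu_lo < 1 + 1e-8) break
  }
  c_fin <- solve_pen(mu_hi, c_cur)
  list(c = c_fin, gain = sum(c_fin * g) - gain_baseline,
       kinship = qKq(c_fin), mode = mode, status = "optimal")
}

#' Realize contributions as a mating plan
#'
#' Each offspring draws its sire with probability `2 c_sire` and its dam
#' with probability `2 c_dam`, independently, so realized parental gene
#' contributions converge to `c` as the offspring count grows.
#'
#' @param c contribution vector (males sum 0.5, females sum 0.5).
#' @param sex candidate sexes (`"M"` / `"F"`).
#' @param ids candidate individual ids.
#' @param n_offspring total offspring to produce.
#' @return `MatingPlan` data.frame (`sire`, `dam`, `n_offspring`).
#' @export
realize_contributions <- function(c, sex, ids, n_offspring) {
  stopifnot(length(c) == length(sex), length(c) == length(ids))
  if (n_offspring == 0)
    return(data.frame(sire = integer(0), dam = integer(0),
                      n_offspring = integer(0)))
  pm <- c[sex == "M"]; pf <- c[sex == "F"]
  if (sum(pm) <= 0 || sum(pf) <= 0)
    stop("realization error: a sex class has zero total contribution")
  male_ids <- ids[sex == "M"]; female_ids <- ids[sex == "F"]
  sire <- male_ids[sample.int(length(male_ids), n_offspring, replace = TRUE,
                              prob = pm)]
  dam <- female_ids[sample.int(length(female_ids), n_offspring, replace = TRUE,
                               prob = pf)]
  agg <- stats::aggregate(list(n_offspring = rep(1L, n_offspring)),
                          by = list(sire = sire, dam = dam), FUN = sum)
  agg[order(-agg$n_offspring), , drop = FALSE]
}
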