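# Heteroscedastic statistics layer: Welch one-way ANOVA, an internally
# implemented studentized-range distribution, the Games-Howell post-hoc
# test, replicate correlation, variance tests, intra-plate variance, and
# the replicate-equivalence calculation. Tests operate on position-level
# readouts (wells/spots), not replicate means.

# Normalise input into group summaries (label, n, mean, var).
group_summaries <- function(x, g = NULL) {
  if (is.data.frame(x) && all(c("n", "mean", "var") %in% names(x))) {
    out <- data.frame(label = if ("label" %in% names(x))
      as.character(x$label) else as.character(seq_len(nrow(x))),
      n = x$n, mean = x$mean, var = x$var, stringsAsFactors = FALSE)
    return(out)
  }
  groups <- if (is.list(x) && is.null(g)) x
  else split(as.numeric(x), g)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- as.character(seq_along(groups))
  data.frame(label = names(groups),
             n = vapply(groups, length, 0L),
             mean = vapply(groups, mean, 0),
             var = vapply(groups, var, 0), stringsAsFactors = FALSE)
}

check_groups <- function(s, min_n = 2) {
  if (nrow(s) < 2) stop("need at least 2 groups")
  if (any(s$n < min_n)) stop("every group needs at least ", min_n,
                             " observations")
  if (any(s$var <= 0)) stop("zero-variance group: ",
                            paste(s$label[s$var <= 0], collapse = ", "))
  s
}

#' Welch one-way ANOVA
#'
#' Heteroscedasticity-robust one-way analysis of variance (Welch 1951):
#' with weights `w_i = n_i / s_i^2`, the statistic is the weighted
#' between-group mean square divided by `1 + 2(k-2)/(k^2-1) * Lambda`, with
#' `Lambda = sum((1 - w_i/W)^2 / (n_i - 1))`, on `(k - 1, (k^2-1)/(3 Lambda))`
#' degrees of freedom.
#'
#' @param x a list of numeric vectors, a numeric vector (with `g`), or a
#'   data.frame of group summaries with columns `n`, `mean`, `var`.
#' @param g optional grouping factor when `x` is a vector.
#' @return A list of class `"welch_anova"`: `statistic`, `df1`, `df2`,
#'   `p.value`, `summaries`.
#' @export
welch_anova <- function(x, g = NULL) {
  s <- check_groups(group_summaries(x, g))
  k <- nrow(s)
  w <- s$n / s$var
  W <- sum(w)
  mw <- sum(w * s$mean) / W
  lambda <- sum((1 - w / W)^2 / (s$n - 1))
  f <- (sum(w * (s$mean - mw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df2 <- (k^2 - 1) / (3 * lambda)
  structure(list(statistic = f, df1 = k - 1, df2 = df2,
                 p.value = pf(f, k - 1, df2, lower.tail = FALSE),
                 summaries = s), class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch one-way ANOVA: F = %.4f, df = (%d, %.2f), p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' Studentized range distribution function
#'
#' `P(Q <= q)` for the range of `k` independent standard normals divided by
#' an independent chi estimate of scale on `df` degrees of freedom, by
#' two-level numerical integration (Gauss-Legendre over the scale
#' distribution, a normal-range integral inside) with panel doubling until
#' successive refinements agree to `tol`.
#'
#' @param q quantile(s), >= 0.
#' @param k number of groups, >= 2.
#' @param df error degrees of freedom, > 0.
#' @param tol absolute refinement tolerance.
#' @return Probabilities in `[0, 1]`.
#' @export
studentized_range_cdf <- function(q, k, df, tol = 1e-8) {
  if (any(q < 0)) stop("q must be non-negative")
  if (k < 2) stop("k must be >= 2")
  if (df <= 0) stop("df must be positive")
  vapply(q, srange_cdf_scalar, 0, k = k, df = df, tol = tol)
}

srange_cdf_scalar <- function(q, k, df, tol) {
  if (q == 0) return(0)
  s_lo <- sqrt(qchisq(1e-14, df) / df)
  s_hi <- sqrt(qchisq(1e-14, df, lower.tail = FALSE) / df)
  # log chi-scale density of s = sigma_hat / sigma
  log_fs <- function(s)
    log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
      (df - 1) * log(s) - df * s^2 / 2
  eval_once <- function(n_out, n_in) {
    go <- pracma::gaussLegendre(n_out, s_lo, s_hi)
    gi <- pracma::gaussLegendre(n_in, -9, 9)
    w <- q * go$x                       # range scaled by each s node
    pz <- pnorm(gi$x)
    dz <- dnorm(gi$x)
    # inner integral for every w: k * int phi(z) (Phi(z) - Phi(z-w))^(k-1)
    pzw <- pnorm(outer(gi$x, w, "-"))   # Phi(z - w): n_in x n_out
    inner <- k * colSums((gi$w * dz) * pmax(pz - pzw, 0)^(k - 1))
    sum(go$w * exp(log_fs(go$x)) * inner)
  }
  n <- 32L
  last <- eval_once(n, 2L * n)
  repeat {
    n <- 2L * n
    cur <- eval_once(n, 2L * n)
    if (abs(cur - last) < tol || n >= 1024L) break
    last <- cur
  }
  min(max(cur, 0), 1)
}

#' Games-Howell post-hoc test
#'
#' All pairwise comparisons with unequal-variance standard errors
#' `sqrt(s_i^2/n_i + s_j^2/n_j)`, Welch-Satterthwaite degrees of freedom,
#' `q = sqrt(2) |mean_i - mean_j| / SE`, and p-values from the studentized
#' range distribution with `k` = total number of groups (family-adjusted by
#' construction; no further correction is applied).
#'
#' @inheritParams welch_anova
#' @param alpha significance threshold used only for the `significant`
#'   flag.
#' @param tol tolerance passed to [studentized_range_cdf()].
#' @return data.frame of class `"games_howell"`: `group1`, `group2`,
#'   `diff`, `se`, `df`, `q`, `p.value`, `significant`.
#' @export
games_howell <- function(x, g = NULL, alpha = 0.05, tol = 1e-8) {
  s <- check_groups(group_summaries(x, g))
  k <- nrow(s)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    vi <- s$var[i] / s$n[i]
    vj <- s$var[j] / s$n[j]
    se <- sqrt(vi + vj)
    df_ij <- (vi + vj)^2 / (vi^2 / (s$n[i] - 1) + vj^2 / (s$n[j] - 1))
    diff <- s$mean[i] - s$mean[j]
    qstat <- sqrt(2) * abs(diff) / se
    p <- 1 - studentized_range_cdf(qstat, k, df_ij, tol = tol)
    c(diff = diff, se = se, df = df_ij, q = qstat, p = min(max(p, 0), 1))
  })
  out <- data.frame(group1 = s$label[pairs[1, ]],
                    group2 = s$label[pairs[2, ]],
                    diff = res["diff", ], se = res["se", ], df = res["df", ],
                    q = res["q", ], p.value = res["p", ],
                    stringsAsFactors = FALSE)
  out$significant <- out$p.value < alpha
  class(out) <- c("games_howell", "data.frame")
  out
}

#' Pearson correlation between replicates
#'
#' Pairs position-level readouts across replicates on (condition, position)
#' and reports every pairwise Pearson correlation plus their mean (the
#' replicate-agreement summary used to compare platforms).
#'
#' @param positions position-level readout table.
#' @param value readout column name (e.g. `"frac_spindle"`).
#' @return A list: `pairwise` (data.frame rep_a, rep_b, r, n) and `r` (mean
#'   pairwise correlation).
#' @export
pearson_between_replicates <- function(positions, value = "frac_spindle") {
  stopifnot(value %in% names(positions))
  wide <- stats::reshape(positions[, c("replicate", "position", value)],
                         idvar = "position", timevar = "replicate",
                         direction = "wide")
  reps <- sort(unique(positions$replicate))
  cols <- paste0(value, ".", reps)
  wide <- wide[stats::complete.cases(wide[, cols, drop = FALSE]), ]
  if (nrow(wide) < 3) stop("need at least 3 matched positions")
  pairs <- utils::combn(length(reps), 2)
  pw <- apply(pairs, 2, function(ij) {
    a <- wide[[cols[ij[1]]]]
    b <- wide[[cols[ij[2]]]]
    if (sd(a) == 0 || sd(b) == 0)
      stop("zero variance in replicate ", reps[ij[1]], " or ", reps[ij[2]])
    stats::cor(a, b)
  })
  list(pairwise = data.frame(rep_a = reps[pairs[1, ]],
                             rep_b = reps[pairs[2, ]], r = pw,
                             n = nrow(wide)),
       r = mean(pw))
}

#' Bartlett test of homogeneity of variances
#'
#' Thin wrapper around the standard chi-square Bartlett statistic with
#' `k - 1` degrees of freedom, applied to a list of groups.
#'
#' @inheritParams welch_anova
#' @return A list: `statistic`, `df`, `p.value`.
#' @export
bartlett_groups <- function(x, g = NULL) {
  groups <- if (is.list(x) && is.null(g)) x else split(as.numeric(x), g)
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 observations")
  if (any(vapply(groups, var, 0) <= 0)) stop("zero-variance group")
  bt <- stats::bartlett.test(groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p.value = bt$p.value)
}

#' Two-sided variance F-test
#'
#' `s_a^2 / s_b^2` against `F(n_a - 1, n_b - 1)` with two-sided p-value
#' `2 * min(tail, 1 - tail)`.
#'
#' @param a,b numeric samples.
#' @return A list: `statistic`, `df`, `p.value`.
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per sample")
  if (var(a) <= 0 || var(b) <= 0) stop("zero-variance sample")
  vt <- stats::var.test(a, b)
  list(statistic = unname(vt$statistic),
       df = unname(vt$parameter), p.value = vt$p.value)
}

#' Intra-plate variance
#'
#' Variance of position-level readouts within each replicate (per
#' condition), averaged across replicates -- the within-plate precision
#' measure used to compare platforms.
#'
#' @param positions position-level readout table.
#' @param value readout column name.
#' @return data.frame: `condition`, `n_replicates`, `intra_plate_var`.
#'   Replicates with fewer than 2 positions for a condition are excluded
#'   with a warning.
#' @export
intra_plate_variance <- function(positions, value = "frac_spindle") {
  stopifnot(value %in% names(positions))
  out <- list()
  for (cn in unique(positions$condition)) {
    vars <- c()
    for (rep_ in unique(positions$replicate)) {
      v <- positions[[value]][positions$condition == cn &
                                positions$replicate == rep_]
      v <- v[!is.na(v)]
      if (length(v) < 2) {
        warning("condition ", cn, " replicate ", rep_,
                ": fewer than 2 positions; excluded")
        next
      }
      vars <- c(vars, var(v))
    }
    out[[cn]] <- data.frame(condition = cn, n_replicates = length(vars),
                            intra_plate_var = mean(vars),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare platform variability
#'
#' Pools position-level readouts of one condition across replicates on each
#' platform and applies the two-sided variance F-test.
#'
#' @param positions_a,positions_b position-level tables of the two
#'   platforms.
#' @param value readout column name.
#' @param condition condition to compare (default: all shared conditions,
#'   one test per condition).
#' @return data.frame: `condition`, `statistic`, `p.value`.
#' @export
platform_variance_test <- function(positions_a, positions_b,
                                   value = "frac_spindle",
                                   condition = NULL) {
  conds <- if (is.null(condition))
    intersect(unique(positions_a$condition), unique(positions_b$condition))
  else condition
  res <- lapply(conds, function(cn) {
    a <- positions_a[[value]][positions_a$condition == cn]
    b <- positions_b[[value]][positions_b$condition == cn]
    ft <- variance_f_test(a[!is.na(a)], b[!is.na(b)])
    data.frame(condition = cn, statistic = ft$statistic,
               p.value = ft$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Replicate-equivalence calculation
#'
#' Number of cell-array replicates needed to reach the standard error
#' obtained with `n_w` multi-well replicates:
#' `n_a = (Var_a / Var_w) * n_w`. The exact value and its ceiling (for
#' planning) are both returned.
#'
#' @param var_a cell-array variance.
#' @param var_w multi-well variance (> 0).
#' @param n_w number of multi-well replicates (>= 1).
#' @return A list of class `"replicate_equivalence"`: `var_a`, `var_w`,
#'   `n_w`, `n_a_exact`, `n_a_ceiling`.
#' @export
replicates_needed <- function(var_a, var_w, n_w) {
  if (var_w <= 0) stop("var_w must be positive")
  if (n_w < 1) stop("n_w must be >= 1")
  if (var_a < 0) stop("var_a must be non-negative")
  exact <- var_a / var_w * n_w
  structure(list(var_a = var_a, var_w = var_w, n_w = n_w,
                 n_a_exact = exact, n_a_ceiling = ceiling(exact)),
            class = "replicate_equivalence")
}

#' @export
print.replicate_equivalence <- function(x, ...) {
  cat(sprintf("replicate equivalence: n_a = %.4f (ceiling %d) for n_w = %g\n",
              x$n_a_exact, x$n_a_ceiling, x$n_w))
  invisible(x)
}

#' Statistics report over a readout table
#'
#' Convenience layer: Welch ANOVA across conditions, Games-Howell pairwise
#' comparisons, per-condition intra-plate variance, and replicate
#' correlation, all on position-level readouts.
#'
#' @param positions position-level readout table.
#' @param value readout column.
#' @param alpha significance threshold for summary flags.
#' @return A list: `anova`, `posthoc`, `intra_plate`, `replicate_cor`.
#' @export
stats_report <- function(positions, value = "frac_spindle", alpha = 0.05) {
  ok <- !is.na(positions[[value]])
  av <- welch_anova(positions[[value]][ok], positions$condition[ok])
  gh <- games_howell(positions[[value]][ok], positions$condition[ok],
                     alpha = alpha)
  ip <- intra_plate_variance(positions, value)
  rc <- tryCatch(pearson_between_replicates(positions, value),
                 error = function(e) NULL)
  list(anova = av, posthoc = gh, intra_plate = ip, replicate_cor = rc)
}
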