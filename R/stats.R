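## Inferential layer: two-sample Monte-Carlo permutation tests with a
## standardized linear statistic, and the speed-wind / wind-route regressions.

#' Two-sample Monte-Carlo permutation test
#'
#' Tests a difference between two groups with the standardized linear
#' statistic T = sum of group A, Z = (T - E[T]) / sqrt(Var[T]) with the
#' moments computed exactly under the permutation null. The two-sided p is
#' the proportion of resampled |Z*| >= |Z| over `n_resamples` Monte-Carlo
#' resamplings; when the number of distinct arrangements is at most
#' `exact_max`, the null is enumerated exhaustively instead.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param n_resamples Monte-Carlo resamples (9999 by convention).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param exact_max Enumerate exhaustively when choose(n, n_a) <= this.
#' @param floor_p Floor the Monte-Carlo p at 1/n_resamples (the raw
#'   proportion is used, not the +1 correction).
#' @return List of class `flytrack_permtest`: `Z`, `p`, `n_resamples`
#'   (`NA` on the exact path), `exact`, `seed`.
#' @export
permutation_test <- function(a, b, n_resamples = 9999, seed = 1L,
                             exact_max = 20000, floor_p = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  x <- c(a, b)
  n <- length(x); na <- length(a)
  mu <- mean(x)
  s2 <- sum((x - mu)^2) / n
  v <- na * (n - na) / (n - 1) * s2
  if (v < 1e-12) {
    return(structure(list(Z = 0, p = 1, n_resamples = NA_integer_,
                          exact = TRUE, seed = seed),
                     class = "flytrack_permtest"))
  }
  zstat <- function(t) (t - na * mu) / sqrt(v)
  z_obs <- zstat(sum(a))
  if (choose(n, na) <= exact_max) {
    idx <- utils::combn(n, na)
    t_all <- colSums(matrix(x[idx], nrow = na))
    p <- mean(abs(zstat(t_all)) >= abs(z_obs) - 1e-12)
    return(structure(list(Z = z_obs, p = p, n_resamples = NA_integer_,
                          exact = TRUE, seed = seed),
                     class = "flytrack_permtest"))
  }
  set.seed(seed)
  t_star <- vapply(seq_len(n_resamples),
                   function(i) sum(x[sample.int(n, na)]), numeric(1))
  p <- mean(abs(zstat(t_star)) >= abs(z_obs) - 1e-12)
  if (floor_p) p <- max(p, 1 / n_resamples)
  structure(list(Z = z_obs, p = p, n_resamples = n_resamples,
                 exact = FALSE, seed = seed),
            class = "flytrack_permtest")
}

#' @export
print.flytrack_permtest <- function(x, ...) {
  cat(sprintf("<permutation test> Z = %.4f, P = %.4f (%s)\n", x$Z, x$p,
              if (x$exact) "exact enumeration"
              else sprintf("%d Monte-Carlo resamples", x$n_resamples)))
  invisible(x)
}

# tidy one-row summary of a fitted lm
.lm_result <- function(fit) {
  s <- summary(fit)
  co <- stats::coef(s)
  if (stats::var(stats::model.response(stats::model.frame(fit))) < 1e-24) {
    s$r.squared <- 0
    s$fstatistic <- NULL
  }
  fs <- s$fstatistic
  if (is.null(fs)) fs <- c(NA_real_, NA_real_, NA_real_)
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             F = fs[1], df1 = fs[2], df2 = fs[3],
             p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
             r_squared = s$r.squared, row.names = NULL)
}

#' Regress flight speed on wind support
#'
#' Ordinary least squares of ground speed or airspeed (km/h) on wind support
#' (km/h) at one pressure level; the slope is the change in speed per km/h
#' of additional tailwind.
#'
#' @param speed Numeric response (km/h), e.g. retained ground speeds.
#' @param support Numeric wind support (km/h), paired with `speed`.
#' @return data.frame with one row per model term: `estimate`, `se`, and
#'   model-level `F`, `df1`, `df2`, `p`, `r_squared`.
#' @export
fit_speed_wind <- function(speed, support) {
  stopifnot(length(speed) == length(support), length(speed) >= 3)
  .lm_result(stats::lm(speed ~ support))
}

#' Wind support by route and direction
#'
#' OLS of wind support on route + direction + interaction, with the eastern
#' route and northward migration as reference levels.
#'
#' @param support Numeric wind support (km/h).
#' @param route Factor/character: `"eastern"` or `"himalayan"`.
#' @param direction Factor/character: `"north"` or `"south"`.
#' @return data.frame as in [fit_speed_wind()].
#' @export
fit_wind_route_direction <- function(support, route, direction) {
  route <- stats::relevel(factor(route), ref = "eastern")
  direction <- stats::relevel(factor(direction), ref = "north")
  if (nlevels(route) < 2 || nlevels(direction) < 2)
    stop("both factors need two levels present")
  .lm_result(stats::lm(support ~ route * direction))
}

#' Correlate northward and southward migration durations
#'
#' Per-bird OLS of northward on southward duration, optionally excluding
#' flagged outlier individuals.
#'
#' @param north,south Paired per-bird durations (days).
#' @param exclude Optional logical vector marking birds to drop.
#' @return List: `r_squared`, `p`, `slope`, `n`.
#' @export
correlate_durations <- function(north, south, exclude = NULL) {
  stopifnot(length(north) == length(south))
  if (!is.null(exclude)) { north <- north[!exclude]; south <- south[!exclude] }
  fit <- .lm_result(stats::lm(north ~ south))
  list(r_squared = fit$r_squared[1], p = fit$p[1],
       slope = fit$estimate[fit$term == "south"], n = length(north))
}
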