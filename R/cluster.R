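#' Find suprathreshold clusters in a t-map
#'
#' Thresholds a map of t-values at the two-tailed critical value for
#' `alpha_cluster` and groups suprathreshold points by contiguity --
#' adjacent points for a 1-D time course, 4-connectivity for a 2-D
#' time-frequency map. Positive and negative excursions form separate
#' clusters; a cluster's statistic is the sum of its member t-values.
#'
#' @param tmap Numeric vector (time course) or matrix (frequency x time)
#'   of t-values; `NA` entries are treated as subthreshold.
#' @param df Degrees of freedom of the t-values.
#' @param alpha_cluster Cluster-forming significance threshold.
#' @return A tibble with one row per cluster: member indices (list),
#'   `stat`, `sign`, and for 1-D input the index range.
#' @export
find_clusters <- function(tmap, df, alpha_cluster = 0.05) {
  tcrit <- stats::qt(1 - alpha_cluster / 2, df)
  if (is.matrix(tmap)) {
    return(find_clusters_2d(tmap, tcrit))
  }
  code <- integer(length(tmap))
  code[!is.na(tmap) & tmap > tcrit] <- 1L
  code[!is.na(tmap) & tmap < -tcrit] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) {
    return(tibble::tibble(
      i_start = integer(), i_end = integer(), sign = integer(),
      stat = numeric(), points = list()
    ))
  }
  tibble::tibble(
    i_start = starts[keep],
    i_end = ends[keep],
    sign = r$values[keep],
    stat = mapply(function(s, e) sum(tmap[s:e]), starts[keep], ends[keep]),
    points = mapply(function(s, e) s:e, starts[keep], ends[keep],
      SIMPLIFY = FALSE
    )
  )
}

# 4-connectivity connected components, positive/negative handled separately
find_clusters_2d <- function(tmap, tcrit) {
  lab <- matrix(0L, nrow(tmap), ncol(tmap))
  mask_p <- !is.na(tmap) & tmap > tcrit
  mask_n <- !is.na(tmap) & tmap < -tcrit
  out <- list()
  next_id <- 0L
  for (sgn in c(1L, -1L)) {
    mask <- if (sgn > 0) mask_p else mask_n
    while (any(mask & lab == 0L)) {
      seed <- which(mask & lab == 0L)[1]
      next_id <- next_id + 1L
      frontier <- seed
      lab[seed] <- next_id
      nr <- nrow(tmap)
      while (length(frontier)) {
        i <- (frontier - 1L) %% nr + 1L
        j <- (frontier - 1L) %/% nr + 1L
        cand <- c(
          frontier[i > 1] - 1L, frontier[i < nr] + 1L,
          frontier[j > 1] - nr, frontier[j <= (ncol(tmap) - 1L) * 1L & j < ncol(tmap)] + nr
        )
        cand <- unique(cand[mask[cand] & lab[cand] == 0L])
        lab[cand] <- next_id
        frontier <- cand
      }
      members <- which(lab == next_id)
      out[[next_id]] <- tibble::tibble(
        i_start = NA_integer_, i_end = NA_integer_, sign = sgn,
        stat = sum(tmap[members]), points = list(members)
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      i_start = integer(), i_end = integer(), sign = integer(),
      stat = numeric(), points = list()
    ))
  }
  dplyr::bind_rows(out)
}

#' Corrected p-values from a maximal-cluster null distribution
#'
#' The corrected p of a cluster is the proportion of null maxima at least
#' as large (in absolute value) as the observed cluster statistic, with an
#' add-one correction so that p is never exactly zero:
#' `(1 + #\{null >= |stat|\}) / (1 + n_null)`.
#'
#' @param stats Observed cluster statistics.
#' @param null_max Null distribution of maximal cluster statistics.
#' @return Corrected p-values in `(0, 1]`.
#' @export
corrected_p <- function(stats, null_max) {
  vapply(
    abs(stats),
    function(s) (1 + sum(null_max >= s)) / (1 + length(null_max)),
    numeric(1)
  )
}

# Maximal |cluster sum| of a single t vector (0 when nothing crosses)
max_cluster_stat <- function(tvec, tcrit) {
  max_cluster_stat_rows(matrix(tvec, nrow = 1), tcrit)
}

# Row-wise maximal |cluster sum| for a matrix of t vectors, computed in a
# single pass: rows are concatenated with zero separators so one rle()
# identifies every run, and run sums come from a global cumsum.
max_cluster_stat_rows <- function(tm, tcrit) {
  nr <- nrow(tm)
  nc <- ncol(tm)
  aug <- cbind(tm, 0)
  v <- as.vector(t(aug))
  v[is.na(v)] <- 0
  code <- integer(length(v))
  code[v > tcrit] <- 1L
  code[v < -tcrit] <- -1L
  out <- numeric(nr)
  if (!any(code != 0L)) {
    return(out)
  }
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  cs <- cumsum(v)
  sums <- abs(cs[ends[keep]] - cs[starts[keep]] + v[starts[keep]])
  rows <- (starts[keep] - 1L) %/% (nc + 1L) + 1L
  agg <- vapply(split(sums, rows), max, numeric(1))
  out[as.integer(names(agg))] <- agg
  out
}

#' Null distribution of maximal cluster statistics from per-site shuffles
#'
#' Second level of the two-level permutation scheme: given each site's
#' encoding estimates refitted under shuffled trial-regressor pairings,
#' draws random cross-site combinations (one shuffle index per site,
#' sampled with replacement), computes the across-site t-map of each
#' combination, and records its maximal suprathreshold |cluster sum|.
#'
#' @param betas_shuffle Array `[site, shuffle, point]` of shuffled
#'   encoding estimates.
#' @param n_combinations Number of cross-site combinations.
#' @param seed Seed for the combination draws.
#' @param alpha_cluster Cluster-forming threshold (two-tailed, with
#'   `df = n_sites - 1`).
#' @param chunk Combinations processed per block (memory control).
#' @return Numeric vector of length `n_combinations` with the maximal
#'   absolute cluster statistic of each combination (0 when no point
#'   crosses the threshold).
#' @export
build_null <- function(betas_shuffle, n_combinations = 2000, seed = 1L,
                       alpha_cluster = 0.05, chunk = 500L) {
  d <- dim(betas_shuffle)
  if (is.null(d) || length(d) != 3) {
    abort("`betas_shuffle` must be a [site, shuffle, point] array.")
  }
  n_use <- d[1]
  n_shuffles <- d[2]
  n_t <- d[3]
  if (n_shuffles < 2) abort("`n_shuffles` must be at least 2.")
  tcrit <- stats::qt(1 - alpha_cluster / 2, n_use - 1)
  comb <- with_seed(
    seed,
    matrix(sample.int(n_shuffles, n_combinations * n_use, replace = TRUE),
      n_combinations, n_use
    )
  )
  b_r <- matrix(betas_shuffle, n_use * n_shuffles, n_t)
  null_max <- numeric(n_combinations)
  for (c0 in seq(1L, n_combinations, by = chunk)) {
    cc <- c0:min(c0 + chunk - 1L, n_combinations)
    rid <- t((comb[cc, , drop = FALSE] - 1L) * n_use +
      rep(seq_len(n_use), each = length(cc)))
    g <- array(b_r[as.vector(rid), , drop = FALSE], c(n_use, length(cc), n_t))
    m <- colMeans(g)
    s2 <- colMeans(g^2) - m^2
    s <- sqrt(pmax(s2, 0) * n_use / (n_use - 1))
    tm <- m / (s / sqrt(n_use))
    tm[s < .Machine$double.eps^0.5] <- NA_real_
    null_max[cc] <- max_cluster_stat_rows(tm, tcrit)
  }
  null_max
}

#' Two-level cluster permutation test for band encoding time courses
#'
#' Implements a two-level permutation scheme for across-site significance
#' of trial-wise encoding estimates. First, each site's trial-to-regressor
#' pairing is shuffled `n_shuffles` times and the encoding model refitted
#' (the design Gram matrix is permutation invariant, so each refit is a
#' single projection). Second, `n_combinations` random cross-site
#' combinations are drawn, each picking one shuffle per site, and the
#' maximal suprathreshold cluster statistic of the resulting across-site
#' t-map is collected into a null distribution. Observed clusters are then
#' assigned corrected p-values by [corrected_p()] against the pooled
#' absolute null.
#'
#' @inheritParams encode_band
#' @param n_shuffles Per-site shuffles (level one).
#' @param n_combinations Cross-site combinations (level two).
#' @param seed Seed controlling shuffles and combinations.
#' @param alpha_cluster Cluster-forming threshold.
#' @param time_range Optional `c(from, to)` restriction of the tested
#'   time axis.
#' @param test_regressors Regressors whose maps receive the permutation
#'   null and corrected p-values (all of `regressors` by default); the
#'   remaining maps report observed clusters with `pc = NA`. The
#'   family-wise correction is per map, so restricting this only skips
#'   work.
#' @return A `cluster_result`: per-regressor tibbles of clusters with
#'   corrected p, the observed t-maps, the null distributions, and
#'   metadata. Supports [tidy()].
#' @export
cluster_correct <- function(bp, condition = "reward",
                            regressors = c("z_q", "z_r"), valid = NULL,
                            n_shuffles = 100, n_combinations = 2000,
                            seed = 1L, alpha_cluster = 0.05,
                            min_trials = 20, time_range = NULL,
                            test_regressors = regressors) {
  if (n_shuffles < 2) abort("`n_shuffles` must be at least 2.")
  trials <- bp$trials
  n_sites <- length(bp$series)

  t_keep <- seq_along(bp$times)
  if (!is.null(time_range)) {
    t_keep <- which(bp$times >= time_range[1] & bp$times <= time_range[2])
  }

  site_data <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    rows <- which(trials$patient_id == bp$sites$patient_id[i])
    keep <- rep(TRUE, length(rows))
    if (!is.null(condition)) keep <- trials$condition[rows] == condition
    if (!is.null(valid)) keep <- keep & valid[[i]]
    x <- as.matrix(trials[rows, regressors])
    keep <- keep & !apply(is.na(x), 1, any)
    if (sum(keep) < max(min_trials, ncol(x) + 4)) next
    y <- bp$series[[i]][keep, t_keep, drop = FALSE]
    ok_t <- !apply(is.na(y), 2, any)
    site_data[[i]] <- list(x = x[keep, , drop = FALSE], y = y, ok_t = ok_t)
  }
  used <- which(!vapply(site_data, is.null, logical(1)))
  if (length(used) < 2) abort("Fewer than 2 sites have enough usable trials.")
  ok_t <- Reduce(`&`, lapply(site_data[used], `[[`, "ok_t"))
  n_t <- sum(ok_t)
  if (n_t == 0) abort("No time points are valid across all usable sites.")
  times <- bp$times[t_keep][ok_t]

  n_reg <- length(regressors)
  n_use <- length(used)
  df <- n_use - 1
  tcrit <- stats::qt(1 - alpha_cluster / 2, df)

  # observed betas and per-site shuffled betas
  obs <- array(NA_real_, c(n_use, n_reg, n_t))
  shuf <- array(NA_real_, c(n_use, n_shuffles, n_reg, n_t))
  for (ii in seq_along(used)) {
    sd_i <- site_data[[used[ii]]]
    xf <- cbind(1, sd_i$x)
    gram_inv <- solve(crossprod(xf))
    y <- sd_i$y[, ok_t, drop = FALSE]
    obs[ii, , ] <- (gram_inv %*% crossprod(xf, y))[-1, , drop = FALSE]
    perms <- with_seed(
      substream_seed(seed, "shuffle", used[ii]),
      replicate(n_shuffles, sample.int(nrow(y)))
    )
    # the Gram matrix is permutation invariant, so all shuffled refits
    # reduce to one cross-product with the stacked permuted designs
    x_all <- matrix(xf[as.vector(perms), -1], nrow(y), n_shuffles * n_reg)
    xty <- crossprod(x_all, y) # (shuffle within reg) x time
    int_xty <- colSums(y) # intercept column is unpermuted
    rhs <- rbind(
      matrix(rep(int_xty, each = n_shuffles), 1, n_shuffles * n_t),
      matrix(aperm(array(xty, c(n_shuffles, n_reg, n_t)), c(2, 1, 3)),
        n_reg, n_shuffles * n_t
      )
    )
    bs <- (gram_inv %*% rhs)[-1, , drop = FALSE]
    shuf[ii, , , ] <- aperm(array(bs, c(n_reg, n_shuffles, n_t)), c(2, 1, 3))
  }

  # observed t-maps and clusters
  result <- vector("list", n_reg)
  names(result) <- regressors
  for (r in seq_len(n_reg)) {
    tt <- t_across_sites(obs[, r, , drop = TRUE])
    clusters <- find_clusters(tt$t, df, alpha_cluster)
    if (!(regressors[r] %in% test_regressors)) {
      clusters$pc <- rep(NA_real_, nrow(clusters))
      clusters$t_start <- times[clusters$i_start]
      clusters$t_end <- times[clusters$i_end]
      result[[r]] <- list(
        clusters = clusters, tmap = tt$t, mean_beta = tt$mean,
        null_max = NULL
      )
      next
    }

    null_max <- build_null(
      array(shuf[, , r, ], c(n_use, n_shuffles, n_t)),
      n_combinations = n_combinations,
      seed = substream_seed(seed, "combinations"),
      alpha_cluster = alpha_cluster
    )
    clusters$pc <- corrected_p(clusters$stat, null_max)
    clusters$t_start <- times[clusters$i_start]
    clusters$t_end <- times[clusters$i_end]
    result[[r]] <- list(
      clusters = clusters, tmap = tt$t, mean_beta = tt$mean,
      null_max = null_max
    )
  }

  structure(
    list(
      by_regressor = result, times = times, df = df, tcrit = tcrit,
      condition = condition %||% "all", lock = bp$lock,
      n_shuffles = n_shuffles, n_combinations = n_combinations,
      sites_used = bp$sites$site_id[used], seed = seed
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Two-level cluster permutation (%s, %d sites, %d x %d permutations)\n",
    x$condition, length(x$sites_used), x$n_shuffles, x$n_combinations
  ))
  for (r in names(x$by_regressor)) {
    cl <- x$by_regressor[[r]]$clusters
    sig <- sum(cl$pc < 0.05)
    cat(sprintf(
      "  %s: %d cluster(s), %d with pc < 0.05%s\n", r, nrow(cl), sig,
      if (sig) {
        sprintf(
          " (best: stat %.1f, pc %.4g)",
          cl$stat[which.min(cl$pc)], min(cl$pc)
        )
      } else {
        ""
      }
    ))
  }
  invisible(x)
}
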