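# Migration persistence and phenotype statistics.
#
# Tracks are positions in micron at a fixed sampling interval (the assay
# class emulated images every 30 s for 7 min). Two persistence measures:
# mean-squared displacement from the track start versus time lag, and the
# mean cosine of the angle between the first step and each later step.
# Phenotype fractions between two cell lines are compared with a Welch
# (unequal-variance) two-sided t test on per-experiment fractions.

#' Mean-squared displacement versus lag
#'
#' MSD(lag) = mean over included cells of |r(t0 + lag) - r(t0)|^2 with t0
#' the track start (displacement-from-origin definition). Cells must have
#' moved at least `min_net` micron from their starting position at some
#' point in the track. Mean and SEM are computed across experiment
#' groups.
#'
#' @param tracks data.frame with columns `cell`, `experiment`, `t`
#'   (seconds), `x`, `y` (micron); uniform sampling per cell.
#' @param min_net minimum net displacement for inclusion (micron,
#'   default 5).
#' @return data.frame with `lag` (s), `msd`, `sem`, `n_cells`,
#'   `n_experiments`.
#' @export
mean_squared_displacement <- function(tracks, min_net = 5) {
  per_exp <- list()
  n_cells <- 0
  for (ex in unique(tracks$experiment)) {
    tx <- tracks[tracks$experiment == ex, ]
    cell_msd <- list()
    for (cl in unique(tx$cell)) {
      tc <- tx[tx$cell == cl, ]
      tc <- tc[order(tc$t), ]
      dx <- tc$x - tc$x[1]; dy <- tc$y - tc$y[1]
      net <- sqrt(dx^2 + dy^2)
      if (max(net) < min_net) next
      cell_msd[[length(cell_msd) + 1]] <-
        data.frame(lag = tc$t - tc$t[1], sq = net^2)[-1, ]
      n_cells <- n_cells + 1
    }
    if (length(cell_msd) == 0) next
    all <- do.call(rbind, cell_msd)
    per_exp[[as.character(ex)]] <-
      tapply(all$sq, all$lag, mean)
  }
  if (length(per_exp) == 0) stop("no qualifying cells")
  lags <- sort(unique(as.numeric(unlist(lapply(per_exp, names)))))
  M <- vapply(per_exp, function(v) v[as.character(lags)],
              numeric(length(lags)))
  M <- matrix(M, nrow = length(lags))
  data.frame(lag = lags,
             msd = rowMeans(M, na.rm = TRUE),
             sem = apply(M, 1, function(v)
               if (sum(is.finite(v)) > 1)
                 stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
               else NA_real_),
             n_cells = n_cells,
             n_experiments = ncol(M))
}

#' Directional persistence: mean cosine to the first step
#'
#' Per cell the reference direction is the first 30 s step; for each
#' subsequent frame-to-frame step the cosine of the angle to the
#' reference is recorded. Cells whose first step is shorter than
#' `min_first_step` micron are excluded; later zero-length steps are
#' skipped (no cosine term). Mean per lag over cells, SEM across
#' experiments.
#'
#' @param tracks data.frame as in [mean_squared_displacement()].
#' @param min_first_step minimum first-step displacement (micron,
#'   default 5).
#' @return data.frame with `lag` (s), `mean_cos`, `sem`, `n_cells`,
#'   `n_experiments`.
#' @export
persistence_cosine <- function(tracks, min_first_step = 5) {
  per_exp <- list()
  n_cells <- 0
  for (ex in unique(tracks$experiment)) {
    tx <- tracks[tracks$experiment == ex, ]
    rows <- list()
    for (cl in unique(tx$cell)) {
      tc <- tx[tx$cell == cl, ]
      tc <- tc[order(tc$t), ]
      if (nrow(tc) < 3) next
      sx <- diff(tc$x); sy <- diff(tc$y)
      len <- sqrt(sx^2 + sy^2)
      if (len[1] < min_first_step) next
      ref <- c(sx[1], sy[1]) / len[1]
      keep <- which(len[-1] > 0) + 1
      if (length(keep) == 0) next
      cosv <- (sx[keep] * ref[1] + sy[keep] * ref[2]) / len[keep]
      rows[[length(rows) + 1]] <-
        data.frame(lag = tc$t[keep + 1] - tc$t[1], cosv = cosv)
      n_cells <- n_cells + 1
    }
    if (length(rows) == 0) next
    all <- do.call(rbind, rows)
    per_exp[[as.character(ex)]] <- tapply(all$cosv, all$lag, mean)
  }
  if (length(per_exp) == 0) stop("no qualifying cells")
  lags <- sort(unique(as.numeric(unlist(lapply(per_exp, names)))))
  M <- vapply(per_exp, function(v) v[as.character(lags)],
              numeric(length(lags)))
  M <- matrix(M, nrow = length(lags))
  data.frame(lag = lags,
             mean_cos = rowMeans(M, na.rm = TRUE),
             sem = apply(M, 1, function(v)
               if (sum(is.finite(v)) > 1)
                 stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
               else NA_real_),
             n_cells = n_cells,
             n_experiments = ncol(M))
}

#' Welch test on per-experiment phenotype fractions
#'
#' Converts per-experiment (positives, totals) counts to fractions and
#' compares the two groups with a two-sided unequal-variance t test
#' (Welch-Satterthwaite degrees of freedom) plus a 95% confidence
#' interval on the difference of means.
#'
#' @param counts_a,counts_b data.frames (or lists) with `positives` and
#'   `totals` per experiment, or plain numeric vectors of fractions.
#' @return list with `mean_a`, `mean_b`, `sem_a`, `sem_b`, `t`, `df`,
#'   `p`, `ci` (95% CI on mean_a - mean_b), `fractions_a`, `fractions_b`.
#' @export
phenotype_fraction_test <- function(counts_a, counts_b) {
  frac <- function(x) {
    if (is.numeric(x)) return(x)
    x <- as.data.frame(x)
    x$positives / x$totals
  }
  fa <- frac(counts_a); fb <- frac(counts_b)
  if (length(fa) < 2 || length(fb) < 2)
    stop("insufficient replication: need >= 2 experiments per group")
  if (stats::var(fa) == 0 && stats::var(fb) == 0 && mean(fa) == mean(fb))
    return(list(mean_a = mean(fa), mean_b = mean(fb),
                sem_a = 0, sem_b = 0, t = 0, df = length(fa) + length(fb) - 2,
                p = 1, ci = c(0, 0), fractions_a = fa, fractions_b = fb))
  tt <- stats::t.test(fa, fb, var.equal = FALSE,
                      alternative = "two.sided", conf.level = 0.95)
  list(mean_a = mean(fa), mean_b = mean(fb),
       sem_a = stats::sd(fa) / sqrt(length(fa)),
       sem_b = stats::sd(fb) / sqrt(length(fb)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int),
       fractions_a = fa, fractions_b = fb)
}

#' Simulate migration tracks (ballistic, Brownian, or persistent)
#'
#' Generator for migration-statistics validation: straight-line tracks at
#' constant speed, Brownian tracks with diffusion constant `D`
#' (independent Gaussian steps of variance 2 D dt per axis), or a
#' persistent random walk.
#'
#' @param n_cells number of cells.
#' @param n_steps steps per track (default 14: 7 min at 30 s).
#' @param interval sampling interval (s, default 30).
#' @param mode "ballistic", "brownian", or "persistent".
#' @param speed ballistic/persistent speed (micron/s).
#' @param D Brownian diffusion constant (micron^2/s).
#' @param persistence_time heading correlation time (s).
#' @param n_experiments experiments the cells are split over.
#' @param seed RNG seed.
#' @return track data.frame for [mean_squared_displacement()].
#' @export
simulate_tracks <- function(n_cells, n_steps = 14, interval = 30,
                            mode = c("ballistic", "brownian", "persistent"),
                            speed = 0.2, D = 1, persistence_time = 120,
                            n_experiments = 4, seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      t <- (0:n_steps) * interval
      if (mode == "ballistic") {
        th <- stats::runif(1, 0, 2 * pi)
        x <- speed * t * cos(th); y <- speed * t * sin(th)
      } else if (mode == "brownian") {
        x <- cumsum(c(0, stats::rnorm(n_steps, 0, sqrt(2 * D * interval))))
        y <- cumsum(c(0, stats::rnorm(n_steps, 0, sqrt(2 * D * interval))))
      } else {
        th <- stats::runif(1, 0, 2 * pi)
        dx <- dy <- numeric(n_steps)
        for (k in seq_len(n_steps)) {
          th <- th + sqrt(2 * interval / persistence_time) * stats::rnorm(1)
          dx[k] <- speed * interval * cos(th)
          dy[k] <- speed * interval * sin(th)
        }
        x <- cumsum(c(0, dx)); y <- cumsum(c(0, dy))
      }
      rows[[i]] <- data.frame(
        cell = i, experiment = ((i - 1) %% n_experiments) + 1,
        t = t, x = x, y = y)
    }
    do.call(rbind, rows)
  })
}
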