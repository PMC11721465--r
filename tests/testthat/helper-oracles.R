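# Independent oracles. These deliberately re-derive everything from
# first principles (own scale table, plain loops, grid searches) so they
# share no code path with the implementation they check.

# own copy of the Kyte-Doolittle table (typed in independently)
.orc_kd <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
             G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
             H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
             R = -4.5)

# brute-force screen: every window, both orientations, scores recomputed
# from the raw table with explicit loops
oracle_screen <- function(motif, target) {
  m <- strsplit(motif, "")[[1]]
  t_ <- strsplit(target, "")[[1]]
  L <- length(m); n <- length(t_)
  rows <- list()
  for (orient in c("forward", "reverse")) {
    mm <- if (orient == "forward") m else rev(m)
    hm <- unname(.orc_kd[mm])
    for (s in 1:(n - L + 1)) {
      hw <- unname(.orc_kd[t_[s:(s + L - 1)]])
      opp <- 0; tot <- 0
      for (i in 1:L) {
        tot <- tot + 1
        if (sign(hm[i]) != sign(hw[i])) opp <- opp + 1
      }
      pm <- 100 * opp / tot
      C <- sum(abs(hm - hw)) / (L * 9)
      rows[[length(rows) + 1]] <- data.frame(
        orientation = orient, window_start = s,
        percent_match = pm, degree = C,
        passes = pm > 75 & C > 0.5)
    }
  }
  do.call(rbind, rows)
}

# brute-force steady-state fit: coarse grid over (K_D, R_max) refined by
# golden-section-style bisection on K_D with R_max re-gridded
oracle_isotherm_fit <- function(conc, resp) {
  sse <- function(kd, rmax) sum((resp - rmax * conc / (conc + kd))^2)
  best <- c(NA, NA, Inf)
  kds <- exp(seq(log(min(conc) / 100), log(max(conc) * 100), length.out = 200))
  rms <- seq(0.5 * max(resp), 2 * max(resp), length.out = 200)
  for (kd in kds) for (rm in rms) {
    v <- sse(kd, rm)
    if (v < best[3]) best <- c(kd, rm, v)
  }
  # refine by repeated local bisection around the grid optimum
  for (iter in 1:60) {
    kd <- best[1]; rm <- best[2]
    for (f in c(0.99, 1.01)) {
      v <- sse(kd * f, rm); if (v < best[3]) best <- c(kd * f, rm, v)
      v <- sse(kd, rm * f); if (v < best[3]) best <- c(kd, rm * f, v)
      v <- sse(kd * f, rm * f); if (v < best[3]) best <- c(kd * f, rm * f, v)
      v <- sse(kd * f, rm / f); if (v < best[3]) best <- c(kd * f, rm / f, v)
    }
    for (f in c(0.999, 1.001, 0.9999, 1.0001)) {
      v <- sse(kd * f, rm); if (v < best[3]) best <- c(kd * f, rm, v)
      v <- sse(kd, rm * f); if (v < best[3]) best <- c(kd, rm * f, v)
    }
  }
  list(K_D = best[1], R_max = best[2], sse = best[3])
}

# best single-exponential fit to a dissociation trace (amplitude
# profiled, decay rate by 1-D search); returns relative RMSE
oracle_single_exp_rel_resid <- function(t, r) {
  f <- function(k) {
    e <- exp(-k * t)
    a <- sum(r * e) / sum(e * e)
    sum((r - a * e)^2)
  }
  o <- optimize(function(lk) f(exp(lk)), c(log(1e-7), log(1)))
  sqrt(o$objective / length(r)) / abs(r[1])
}

random_protein <- function(n) {
  paste(sample(names(.orc_kd), n, replace = TRUE), collapse = "")
}
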