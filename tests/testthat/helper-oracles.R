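# Independent brute-force oracles used to cross-check the package's
# optimizer-based fits and filters.  Kept deliberately simple and separate
# from the implementation paths they verify.

# Dense log-grid search over the time constant with the linear parameters
# solved in closed form at each grid point.  Returns the grid optimum and
# the grid step (in log10 units).
oracle_grid_fit <- function(model, t, s, sigma = 0, s_inv = NULL,
                            t_range = c(5, 2000), steps_per_decade = 60,
                            f_grid = seq(0.5, 1, by = 0.005)) {
  Tgrid <- 10^seq(log10(t_range[1]), log10(t_range[2]),
                  by = 1 / steps_per_decade)
  rss_at <- function(T) {
    E <- exp(-t / T)
    if (model == "monoexp") {
      sc <- sqrt(pmax(s^2 - sigma^2, 0))
      S0 <- sum(sc * E) / sum(E^2)
      sum((sc - S0 * E)^2)
    } else if (model == "exp_baseline") {
      X <- cbind(E, 1)
      cf <- qr.solve(X, s)
      sum((s - X %*% cf)^2)
    } else if (model == "ir") {
      min(vapply(f_grid, function(f) {
        g <- abs(1 - 2 * f * E)
        S0 <- sum(s * g) / sum(g^2)
        sum((s - S0 * g)^2)
      }, numeric(1)))
    } else if (model == "raff") {
      # joint plain + folded inverted curves, linear in (SS, S0p, S0i)
      # given T and a fold-sign pattern; the signed inverted curve is
      # monotone so the pattern is -...-+...+ along increasing t
      m <- length(t)
      best <- Inf
      for (kfold in 0:m) {
        sgn <- rep(1, m); if (kfold > 0) sgn[seq_len(kfold)] <- -1
        X <- rbind(cbind(1 - E, E, 0 * E),
                   cbind(sgn * (1 - E), 0 * E, sgn * E))
        y <- c(s, s_inv)
        cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
        if (is.null(cf)) next
        best <- min(best, sum((y - X %*% cf)^2))
      }
      best
    } else stop("unknown oracle model")
  }
  rss <- vapply(Tgrid, rss_at, numeric(1))
  list(T = Tgrid[which.min(rss)], log10_step = 1 / steps_per_decade)
}

# Brute-force local histogram entropy, written independently of
# entropy_filter(): explicit symmetric padding by value copying and a
# table()-based histogram per pixel.
oracle_entropy <- function(x, window = 5L, n_bins = 256L, max_angle = 180) {
  h <- (window - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  big <- matrix(NA_real_, nr + 2 * h, nc + 2 * h)
  big[(h + 1):(h + nr), (h + 1):(h + nc)] <- x %% max_angle
  for (k in seq_len(h)) {   # symmetric reflection, value by value
    big[h + 1 - k, ] <- big[h + k, ]
    big[h + nr + k, ] <- big[h + nr + 1 - k, ]
  }
  for (k in seq_len(h)) {
    big[, h + 1 - k] <- big[, h + k]
    big[, h + nc + k] <- big[, h + nc + 1 - k]
  }
  bin <- pmin(floor(big / max_angle * n_bins), n_bins - 1)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      counts <- table(as.vector(bin[i:(i + 2 * h), j:(j + 2 * h)]))
      p <- counts / sum(counts)
      out[i, j] <- -sum(p * log2(p))
    }
  }
  out
}

# Small phantom spec with a single customized transverse kind, used where a
# test needs hand-set R_iso / c_dip.
spec_with_params <- function(kind = "T2", R_iso = 10, c_dip = 40, ...) {
  rp <- default_relax_params()
  rp$R_iso_s[rp$kind == kind] <- R_iso
  rp$c_dip_s[rp$kind == kind] <- c_dip
  phantom_spec(relax_params = rp, ...)
}
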