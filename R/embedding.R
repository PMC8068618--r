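#' Average mutual information first minimum
#'
#' Computes the average mutual information I(tau) between a series and its
#' lagged copy for tau = 1..max_lag, using an equiprobable-bin (rank-based)
#' histogram estimator, and returns the smallest tau that is a strict local
#' minimum of I. If no local minimum exists within range, the argmin is
#' returned with a warning — the conventional fallback for short series.
#'
#' @param x numeric series.
#' @param max_lag largest lag to scan (samples).
#' @param n_bins number of equiprobable bins per margin (default 16).
#' @param full if TRUE, return the whole AMI profile instead of the lag.
#' @return Integer lag (or, with `full = TRUE`, a data.frame `lag`, `ami`).
#' @export
ami_first_minimum <- function(x, max_lag = 50, n_bins = 16, full = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x)))
    stop("ami_first_minimum: constant or degenerate series", call. = FALSE)
  if (n_bins < 2) stop("ami_first_minimum: n_bins must be >= 2", call. = FALSE)
  if (n <= max_lag + 1) stop("ami_first_minimum: series too short", call. = FALSE)
  # equiprobable binning: bin by rank
  bin <- ceiling(rank(x, ties.method = "first") * n_bins / n)
  a_of_cell <- rep(seq_len(n_bins), times = n_bins)   # joint cell = a + n_bins*(b-1)
  b_of_cell <- rep(seq_len(n_bins), each = n_bins)
  ami <- vapply(seq_len(max_lag), function(tau) {
    a <- bin[seq_len(n - tau)]
    b <- bin[(tau + 1):n]
    joint <- tabulate(a + n_bins * (b - 1L), nbins = n_bins * n_bins)
    p <- joint / sum(joint)
    pa <- tabulate(a, nbins = n_bins) / length(a)
    pb <- tabulate(b, nbins = n_bins) / length(b)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / (pa[a_of_cell[nz]] * pb[b_of_cell[nz]])))
  }, numeric(1))
  if (full) return(data.frame(lag = seq_len(max_lag), ami = ami))
  is_min <- which(diff(sign(diff(ami))) > 0) + 1L   # strict local minima
  if (length(is_min)) return(is_min[1L])
  warning("ami_first_minimum: no strict local minimum up to max_lag; returning argmin")
  which.min(ami)
}

#' Delay-embed a multichannel series
#'
#' Builds the delay-coordinate state matrix: for each channel c and delay
#' j = 0..d_per_channel-1, a coordinate w_c(t - j*tau). State dimension is
#' `channels * d_per_channel`; vector count is `n - (d_per_channel-1)*tau`.
#'
#' @param series numeric vector (1 channel) or matrix (samples x channels).
#' @param tau delay in samples (>= 1).
#' @param d_per_channel number of delayed copies per channel (>= 1).
#' @return Matrix of state vectors (rows), with attributes `tau`,
#'   `d_per_channel`, `channels`.
#' @export
delay_embed <- function(series, tau, d_per_channel) {
  m <- as.matrix(series)
  n <- nrow(m); k <- ncol(m)
  tau <- as.integer(tau); d <- as.integer(d_per_channel)
  if (tau < 1 || d < 1) stop("delay_embed: tau and d_per_channel must be >= 1", call. = FALSE)
  span <- (d - 1L) * tau
  if (n <= span) stop("delay_embed: series too short for embedding window", call. = FALSE)
  nv <- n - span
  out <- matrix(0, nv, k * d)
  col <- 0L
  for (c in seq_len(k)) for (j in 0:(d - 1L)) {
    col <- col + 1L
    out[, col] <- m[(span + 1L - j * tau):(n - j * tau), c]
  }
  structure(out, tau = tau, d_per_channel = d, channels = k)
}

# Nearest neighbour of every state vector, excluding a Theiler window of
# temporal neighbours, by blocked brute-force Euclidean search.
nearest_neighbors <- function(states, theiler = 0L, block = 2000L) {
  n <- nrow(states)
  sq <- rowSums(states^2)
  nn_idx <- integer(n)
  nn_d2 <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    # squared distances block x n
    D2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(states[idx, , drop = FALSE], states)
    for (r in seq_along(idx)) {
      i <- idx[r]
      lo <- max(1L, i - theiler); hi <- min(n, i + theiler)
      D2[r, lo:hi] <- Inf
    }
    j <- max.col(-D2, ties.method = "first")
    nn_idx[idx] <- j
    nn_d2[idx] <- D2[cbind(seq_along(idx), j)]
  }
  list(index = nn_idx, dist = sqrt(pmax(nn_d2, 0)))
}

#' False-nearest-neighbour embedding dimension
#'
#' Kennel's criterion: for each candidate dimension the nearest neighbour
#' of every state vector is found; a neighbour is "false" if adding the
#' next delay coordinate blows the pair apart (distance-ratio test with
#' threshold `rtol`) or beyond the attractor size (`atol_factor` times the
#' series sd). The smallest dimension with a false fraction below
#' `cutoff` is returned; `max_dim` with a warning if never reached.
#'
#' @param x numeric 1-D series.
#' @param tau embedding delay (samples).
#' @param max_dim largest dimension tried (default 10).
#' @param rtol distance-ratio threshold (default 15).
#' @param atol_factor attractor-size threshold factor (default 2).
#' @param cutoff acceptable false-neighbour fraction (default 0.01).
#' @param theiler Theiler window for the neighbour search (default `tau`).
#' @param full if TRUE return the per-dimension false fractions.
#' @return Integer dimension (or a data.frame with `dim`, `fnn_fraction`).
#' @export
fnn_dimension <- function(x, tau, max_dim = 10, rtol = 15, atol_factor = 2,
                          cutoff = 0.01, theiler = tau, full = FALSE) {
  x <- as.numeric(x)
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0)
    stop("fnn_dimension: degenerate series", call. = FALSE)
  fracs <- rep(NA_real_, max_dim)
  for (d in seq_len(max_dim)) {
    span_next <- d * tau                       # need x(t + tau*d) for the test
    n <- length(x)
    if (n <= span_next + 1L) break
    emb <- delay_embed(x, tau, d)
    # align so coordinate for "next dimension" exists: drop last tau vectors
    nv <- nrow(emb) - tau
    if (nv < 10L) break
    emb <- emb[seq_len(nv), , drop = FALSE]
    nn <- nearest_neighbors(emb, theiler = theiler)
    i <- seq_len(nv); j <- nn$index
    # extra coordinate is the sample tau ahead of the newest coordinate
    base <- (d - 1L) * tau                      # embedding span
    xi <- x[base + i + tau]
    xj <- x[base + j + tau]
    dd <- nn$dist
    extra <- abs(xi - xj)
    dnew <- sqrt(dd^2 + extra^2)
    false1 <- extra / pmax(dd, .Machine$double.eps) > rtol
    false2 <- dnew / (atol_factor * sdx) > 1
    fracs[d] <- mean(false1 | false2)
    if (!full && fracs[d] < cutoff) return(as.integer(d))
  }
  if (full) return(data.frame(dim = seq_len(max_dim), fnn_fraction = fracs))
  ok <- which(fracs < cutoff)
  if (length(ok)) return(as.integer(ok[1L]))
  warning("fnn_dimension: false-neighbour fraction never fell below cutoff; returning max_dim")
  as.integer(max_dim)
}
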