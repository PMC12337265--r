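# shared fixture builders and independent oracles

tiny_volume <- function(grid = c(4, 4, 4), n = 64, fs = 10, seed = 1,
                        m = 100, sd = 1) {
  set.seed(seed)
  voxel_volume(array(m + rnorm(prod(grid) * n, 0, sd), c(grid, n)), fs = fs)
}

# per-subject pipeline: trim/high-pass then band CV map
cv_pipeline <- function(band, n_trim = 0) {
  function(vol) cv_map(bandpass_with_mean(
    trim_and_highpass(vol, n_trim = n_trim), band))
}

# brute-force TFCE: explicit cluster labelling at every threshold step via
# igraph connected components (independent of the package's C++ path)
tfce_oracle <- function(stat, mask = NULL, H = 2, E = 0.5, n_steps = 100,
                        connectivity = 26) {
  d <- dim(stat)
  if (is.null(mask)) mask <- array(TRUE, d)
  V <- prod(d)
  coords <- arrayInd(seq_len(V), d)
  mx <- max(stat[mask], 0)
  out <- array(0, d)
  if (mx <= 0) return(out)
  dh <- mx / n_steps
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  for (s in seq_len(n_steps)) {
    h <- s * dh
    sel <- which(mask & stat >= h)
    if (!length(sel)) next
    pos <- rep(NA_integer_, V)
    pos[sel] <- seq_along(sel)
    edges <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nb <- coords[sel, , drop = FALSE] +
        matrix(offs[k, ], length(sel), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      lin <- rep(NA_integer_, length(sel))
      lin[ok] <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) +
        d[1] * d[2] * (nb[ok, 3] - 1)
      tgt <- pos[lin]
      keep <- !is.na(tgt)
      edges <- c(edges, rbind(which(keep), tgt[keep]))
    }
    g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    sizes <- tabulate(comp)
    out[sel] <- out[sel] + sizes[comp]^E * h^H * dh
  }
  out
}

# least-squares projection of a series onto the Fourier basis of the kept
# bins: a frequency-domain filtering oracle independent of the FFT path
fourier_projection_oracle <- function(x, fs, keep) {
  n <- length(x)
  tt <- seq_len(n) - 1
  f <- (0:(n %/% 2)) * fs / n
  cols <- list()
  for (k in which(keep(f))) {
    fk <- f[k]
    cols[[length(cols) + 1]] <- cos(2 * pi * fk * tt / fs)
    if (fk > 0 && fk < fs / 2)
      cols[[length(cols) + 1]] <- sin(2 * pi * fk * tt / fs)
  }
  if (!length(cols)) return(rep(0, n))
  B <- do.call(cbind, cols)
  as.numeric(B %*% solve(crossprod(B), crossprod(B, x)))
}
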