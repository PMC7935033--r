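#' Bin a spike raster onto a common time grid
#'
#' Counts spikes per source in contiguous bins of `bin_width` seconds
#' covering `[0, duration]`. A spike exactly at `duration` lands in the last
#' bin. The counts conserve the spike total.
#'
#' @param raster a [spike_raster()].
#' @param bin_width bin width in seconds (default 0.001, i.e. 1 ms).
#' @return sparse matrix (`Matrix::dgCMatrix`), sources x bins, with the
#'   raster's source ids as row names.
#' @export
bin_raster <- function(raster, bin_width = 0.001) {
  stopifnot(is_spike_raster(raster))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  n_bins <- max(1L, as.integer(ceiling(raster$duration / bin_width - 1e-9)))
  df <- as.data.frame(raster)
  i <- match(df$source_id, names(raster$spikes))
  j <- pmin(floor(df$time_s / bin_width) + 1L, n_bins)
  X <- Matrix::sparseMatrix(i = i, j = j,
                            x = rep(1, length(i)),
                            dims = c(n_sources(raster), n_bins))
  rownames(X) <- names(raster$spikes)
  X
}

#' Build a functional-connectivity network from a spike raster
#'
#' Computes, for every source pair, the normalized cross-correlation of the
#' binned spike trains (1-ms bins by default) at every integer-bin lag
#' within `[-max_lag, +max_lag]` (default 20 ms, restricting edges to
#' short-latency interactions), and takes the maximum over lags as the edge
#' weight. The normalization divides by the product of the two binned
#' vectors' Euclidean norms, so a train that is an exact lag-shifted copy of
#' another scores 1. Because the maximum runs over both lag signs, the
#' resulting matrix is symmetric and the network undirected.
#'
#' Sources with no spikes have undefined correlation; their edges are set to
#' 0 with a warning.
#'
#' @param raster a [spike_raster()] with at least 2 sources.
#' @param bin_width bin width, seconds (default 0.001).
#' @param max_lag maximum latency, seconds (default 0.020).
#' @param mean_subtract if `TRUE`, subtract each binned train's mean before
#'   correlating (Pearson-style); the default `FALSE` keeps raw counts, the
#'   usual spike-train convention.
#' @return object of class `functional_network`: list with the symmetric
#'   zero-diagonal weight matrix `W` (entries in `[0, 1]`), `labels`,
#'   `bin_width`, `max_lag`, `mean_subtract`.
#' @export
build_functional_network <- function(raster, bin_width = 0.001,
                                     max_lag = 0.020,
                                     mean_subtract = FALSE) {
  stopifnot(is_spike_raster(raster))
  if (n_sources(raster) < 2L) stop("need at least 2 sources")
  if (raster$duration <= 2 * max_lag) stop("duration must greatly exceed max_lag")
  X <- bin_raster(raster, bin_width)
  n <- nrow(X)
  B <- ncol(X)
  L <- as.integer(round(max_lag / bin_width))
  s <- Matrix::rowSums(X)
  sq <- Matrix::rowSums(X^2)
  mu <- s / B
  best <- matrix(0, n, n)
  for (l in 0:L) {
    A <- if (l == 0) X else X[, 1:(B - l), drop = FALSE]
    Bm <- if (l == 0) X else X[, (l + 1):B, drop = FALSE]
    M <- as.matrix(Matrix::tcrossprod(A, Bm))   # M[i, j] = sum x_i(t) x_j(t+l)
    if (mean_subtract) {
      left_sum <- Matrix::rowSums(A)    # sum_{t <= B-l} x_i(t)
      right_sum <- Matrix::rowSums(Bm)  # sum_{t > l}   x_j(t)
      M <- M - outer(mu, right_sum) - outer(left_sum, mu) +
        (B - l) * outer(mu, mu)
    }
    best <- pmax(best, M, t(M))
  }
  norms <- if (mean_subtract) sqrt(pmax(sq - B * mu^2, 0)) else sqrt(sq)
  zero <- norms == 0
  norms[zero] <- 1
  W <- best / outer(norms, norms)
  if (any(zero)) {
    warning(sum(zero), " source(s) with no spikes: their edges set to 0")
    W[zero, ] <- 0
    W[, zero] <- 0
  }
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  dimnames(W) <- list(rownames(X), rownames(X))
  structure(list(W = W, labels = rownames(X), bin_width = bin_width,
                 max_lag = max_lag, mean_subtract = mean_subtract),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(paste0("<functional_network> %d nodes, bin %.4g s, max lag ",
                     "%.4g s, mean edge %.4f\n"),
              nrow(x$W), x$bin_width, x$max_lag,
              mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

#' Read and write functional-network weight matrices
#'
#' Square tab-delimited matrix with node labels as header row and first
#' column.
#'
#' @param network a `functional_network` (or bare matrix for
#'   `write_network`).
#' @param path file path.
#' @export
write_network <- function(network, path) {
  W <- if (inherits(network, "functional_network")) network$W else network
  df <- data.frame(node = rownames(W), W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df[[1]]
  storage.mode(W) <- "double"
  W
}
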