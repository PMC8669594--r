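# Instantaneous phases via the analytic signal, sliding-window phase
# locking values between all ROI pairs, and thresholding into weighted
# brain graphs.

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal, computed by the FFT construction of the
#' Hilbert transform (positive frequencies doubled, negative zeroed). The
#' first and last 5% of samples are edge-unreliable and flagged in the
#' `"edge_unreliable"` attribute; phases should be computed on the whole
#' padded epoch and windows drawn from the interior.
#'
#' @param x real numeric vector (band-limited, e.g. MRCP band)
#' @return numeric vector of wrapped phases in radians, with attribute
#'   `edge_unreliable` (logical mask)
#' @export
instantaneous_phase <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (all(x == 0)) stop("phase undefined for an all-zero signal")
  ph <- Arg(analytic_signal(x))
  n <- length(x)
  edge <- ceiling(0.05 * n)
  mask <- rep(FALSE, n)
  mask[seq_len(edge)] <- TRUE
  mask[(n - edge + 1):n] <- TRUE
  attr(ph, "edge_unreliable") <- mask
  ph
}

# analytic signal z = x + i H[x] via the standard FFT one-sided spectrum
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase locking value of two phase series
#'
#' `|mean(exp(i (phi_x - phi_y)))|` over the window: 1 for perfect
#' (constant-lag) locking, near 0 for independent phases.
#'
#' @param phi_x,phi_y equal-length phase vectors in radians (N >= 2)
#' @return scalar in \[0, 1\]
#' @export
plv <- function(phi_x, phi_y) {
  if (length(phi_x) != length(phi_y)) stop("phase window length mismatch")
  stopifnot(length(phi_x) >= 2)
  Mod(mean(exp(1i * (phi_x - phi_y))))
}

#' Sliding-window PLV matrices over ROI pairs
#'
#' Computes instantaneous phases of every ROI time course on the whole
#' padded epoch, then, for a 1-s window slid in 0.1-s steps over the tROI,
#' the 24 x 24 PLV matrix per window. Single-trial PLV matrices are
#' averaged across the trials supplied (pass one condition's trials for a
#' condition-level tensor); set `average = FALSE` to keep per-trial
#' tensors.
#'
#' @param sources a `grasp_sources` at the working rate
#' @param window_s window length in seconds (default 1)
#' @param step_s window step in seconds (default 0.1)
#' @param troi interval (seconds) whose interior the windows cover;
#'   defaults to the tROI
#' @param average average across trials (default `TRUE`)
#' @return object of class `plv_tensor`: `values` (windows x 24 x 24, or
#'   trials x windows x 24 x 24 when `average = FALSE`), `window_centers`
#'   (seconds), `window_s`, `step_s`
#' @export
plv_matrix <- function(sources, window_s = 1, step_s = 0.1, troi = TROI,
                       average = TRUE) {
  data <- sources$data
  rate <- sources$rate
  time <- sources$time
  n_tr <- dim(data)[1]
  n_roi <- dim(data)[2]
  w_n <- as.integer(round(window_s * rate))
  if (w_n > length(time)) stop("epoch shorter than one PLV window")
  span <- troi[2] - troi[1] - window_s
  if (span < 0) stop("tROI shorter than one PLV window")
  n_win <- floor(span / step_s + 1e-9) + 1L
  starts_t <- troi[1] + (seq_len(n_win) - 1) * step_s
  centers <- starts_t + window_s / 2

  vals <- array(0, c(n_tr, n_win, n_roi, n_roi))
  for (i in seq_len(n_tr)) {
    Z <- matrix(0i, n_roi, length(time))
    for (r in seq_len(n_roi)) {
      x <- data[i, r, ]
      if (all(x == 0)) stop("all-zero ROI signal: phase undefined")
      Z[r, ] <- exp(1i * instantaneous_phase(x))
    }
    for (w in seq_len(n_win)) {
      i0 <- grid_index(starts_t[w], time[1], rate)
      idx <- i0:(i0 + w_n - 1L)
      Zw <- Z[, idx, drop = FALSE]
      M <- Mod(Zw %*% Conj(t(Zw))) / w_n
      diag(M) <- 1
      vals[i, w, , ] <- M
    }
  }
  out <- if (average) {
    v <- apply(vals, c(2, 3, 4), mean)
    dimnames(v) <- list(NULL, sources$roi, sources$roi)
    v
  } else vals
  structure(list(values = out, window_centers = centers,
                 window_s = window_s, step_s = step_s,
                 averaged = average, roi = sources$roi),
            class = "plv_tensor")
}

#' Threshold a PLV matrix into a weighted brain graph
#'
#' Keeps undirected edges with weight at or above the threshold (default
#' 0.65, suppressing spurious connections); isolated nodes are retained,
#' self-loops are never created.
#'
#' @param matrix symmetric matrix with entries in \[0, 1\]
#' @param threshold minimum retained edge weight
#' @param labels node labels (default the 24 atlas ROIs when dimensions
#'   match)
#' @return object of class `brain_graph`: `adj` (thresholded weighted
#'   adjacency with zero diagonal), `labels`, `threshold`
#' @export
threshold_graph <- function(matrix, threshold = 0.65, labels = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (max(abs(matrix - t(matrix))) > 1e-8) stop("asymmetric PLV matrix")
  adj <- (matrix + t(matrix)) / 2
  diag(adj) <- 0
  adj[adj < threshold] <- 0
  if (is.null(labels))
    labels <- if (nrow(adj) == 24) grasp_rois() else
      paste0("node", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  structure(list(adj = adj, labels = labels, threshold = threshold),
            class = "brain_graph")
}

# igraph view of a brain_graph (weighted, undirected)
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Export a brain graph as GraphML
#'
#' Writes the weighted graph with ROI labels (and module ids when
#' supplied) as node attributes.
#'
#' @param g a `brain_graph`
#' @param path output file path
#' @param modules optional node -> module id vector
#' @return the path, invisibly
#' @export
write_brain_graph <- function(g, path, modules = NULL) {
  ig <- as_igraph(g)
  igraph::V(ig)$roi <- g$labels
  if (!is.null(modules)) igraph::V(ig)$module <- as.integer(modules)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %d nodes, %d edges (threshold %.2f)\n",
              nrow(x$adj), sum(x$adj > 0) / 2, x$threshold))
  invisible(x)
}

#' @export
print.plv_tensor <- function(x, ...) {
  nw <- length(x$window_centers)
  cat(sprintf("<plv_tensor> %d windows of %g s (step %g s), %s\n",
              nw, x$window_s, x$step_s,
              if (x$averaged) "trial-averaged" else "per-trial"))
  invisible(x)
}
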