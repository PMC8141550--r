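# Induced-fit binding-site geometry: compactness series, running-average
# smoothing, pre/post-binding splits, and the sorted all-vs-all RMSD matrix
# of the coordinating atoms.

#' Binding-site compactness time series
#'
#' Compactness is the mean distance of the coordinating atoms from their
#' unweighted centroid at each sampled frame; smaller values mean a more
#' closed site.  (The atoms mix O and C, whose mass difference is
#' negligible for the ranking; a mass-weighted centroid is available behind
#' `mass_weighted`, off by default.)
#'
#' @param traj a `Trajectory`
#' @param site_selection `AtomSelection` of at least 2 coordinating atoms
#' @param resolution sampling interval, ns (default 0.1, i.e. 100 ps); must
#'   be at least the frame spacing
#' @param mass_weighted use mass-weighted centroid (requires `top`)
#' @param top `Topology`, needed only when `mass_weighted = TRUE`
#' @return data.frame of class `CompactnessSeries` with `time` (ns) and
#'   `value` (nm)
#' @export
compactness_series <- function(traj, site_selection, resolution = 0.1,
                               mass_weighted = FALSE, top = NULL) {
  stopifnot(inherits(traj, "Trajectory"),
            inherits(site_selection, "AtomSelection"))
  idx <- site_selection$indices
  if (length(idx) < 2L)
    stopf("compactness definition error: need at least 2 coordinating atoms")
  if (resolution < traj$dt - 1e-9)
    stopf("compactness_series: resolution %g ns below frame spacing %g ns",
          resolution, traj$dt)
  w <- NULL
  if (mass_weighted) {
    if (is.null(top)) stopf("compactness_series: mass_weighted needs top")
    w <- top$atoms$mass[idx]; w <- w / sum(w)
  }
  stride <- max(1L, as.integer(round(resolution / traj$dt)))
  frames <- seq(1L, traj$n_frames, by = stride)
  vals <- vapply(frames, function(k) {
    p <- traj$coords[k, idx, , drop = FALSE]
    dim(p) <- c(length(idx), 3L)
    ctr <- if (is.null(w)) colMeans(p) else colSums(p * w)
    mean(rownorms(sweep(p, 2L, ctr)))
  }, numeric(1L))
  structure(data.frame(time = traj$times[frames], value = vals),
            class = c("CompactnessSeries", "data.frame"),
            replica_id = traj$replica_id)
}

#' Centered running average of a time series
#'
#' Window truncated at the series edges (so a constant series and the
#' interior of a linear ramp are unchanged); length preserved.
#'
#' @param series data.frame with `time` and `value` (e.g. a
#'   `CompactnessSeries`)
#' @param window window width, ns (default 1.0); must be at least the
#'   series resolution
#' @return series of the same shape with smoothed `value`
#' @export
running_average <- function(series, window = 1.0) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  res <- if (nrow(series) > 1L) series$time[2L] - series$time[1L] else window
  if (window < res - 1e-9)
    stopf("running_average config error: window %g ns shorter than resolution %g ns",
          window, res)
  half <- as.integer(floor(window / (2 * res)))
  n <- nrow(series)
  v <- series$value
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- series
  out$value <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

#' Split a compactness series at the binding time
#'
#' Pre = samples strictly before the binding time, post = samples at or
#' after it; the value at binding is the nearest sample (no interpolation:
#' the signal is sampled, not continuous).  A censored binding time puts
#' every sample in pre and leaves post absent.  Histograms use a 0.005 nm
#' bin width; they are the canonical output any violin plot is drawn from.
#'
#' @param series a `CompactnessSeries` (or any time/value data.frame)
#' @param binding_time ns, or NA for censored
#' @param bin_width histogram bin width, nm
#' @return list of class `SplitSummary`: `pre` and `post` (each
#'   mean/sd/n/histogram, post NULL when censored), `value_at_binding`
#' @export
split_pre_post <- function(series, binding_time, bin_width = 0.005) {
  stopifnot(is.data.frame(series))
  if (length(binding_time %||% numeric()) != 1L) binding_time <- NA_real_
  censored <- is.na(binding_time)
  summ <- function(v) {
    if (!length(v)) return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                                histogram = NULL))
    br <- seq(floor(min(v) / bin_width) * bin_width,
              ceiling(max(v) / bin_width) * bin_width + bin_width,
              by = bin_width)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    list(mean = mean(v), sd = stats::sd(v), n = length(v),
         histogram = data.frame(mid = h$mids, count = h$counts))
  }
  if (censored) {
    out <- list(pre = summ(series$value), post = NULL,
                value_at_binding = NA_real_)
  } else {
    pre <- series$value[series$time < binding_time]
    post <- series$value[series$time >= binding_time]
    out <- list(pre = summ(pre), post = summ(post),
                value_at_binding =
                  series$value[which.min(abs(series$time - binding_time))])
  }
  structure(out, class = "SplitSummary", binding_time = binding_time)
}

#' @export
print.SplitSummary <- function(x, ...) {
  cat(sprintf("SplitSummary: pre n=%d mean=%.3f nm", x$pre$n, x$pre$mean))
  if (!is.null(x$post))
    cat(sprintf("; post n=%d mean=%.3f nm; at binding %.3f nm",
                x$post$n, x$post$mean, x$value_at_binding))
  cat("\n")
  invisible(x)
}

#' All-vs-all RMSD matrix of the coordinating atoms
#'
#' Frames are sampled every `stride` ns from every replica; each pair is
#' superposed on the coordinating atoms themselves before the RMSD
#' (`mode = "pairwise"`, the default: the matrix measures local geometry
#' similarity), or compared in the frame as given (`mode = "global"`, for
#' trajectories already superposed on the protein).  Rows/columns are
#' ordered with bound replicas first by ascending binding time, censored
#' replicas after (by replica id), matching the conventional sorting of
#' such matrices.  Degenerate (collinear) frame pairs are computed without
#' rotation and flagged.
#'
#' @param rset a `ReplicaSet`
#' @param site_selection `AtomSelection` of the coordinating atoms
#' @param first_times data.frame from [first_binding_times()] used for the
#'   ordering; NULL orders by replica id
#' @param stride sampling interval, ns (default 10)
#' @param mode `"pairwise"` or `"global"`
#' @return list of class `RMSDMatrix`: `values` (symmetric, zero diagonal,
#'   nm), `labels` (replica_id, time), `order` (replica ids in row order),
#'   `blocks` (first row index of each replica block), `degenerate`
#'   (logical matrix)
#' @export
rmsd_matrix <- function(rset, site_selection, first_times = NULL,
                        stride = 10, mode = c("pairwise", "global")) {
  stopifnot(inherits(rset, "ReplicaSet"))
  mode <- match.arg(mode)
  idx <- site_selection$indices
  ids <- vapply(rset$trajectories, `[[`, integer(1L), "replica_id")
  if (!is.null(first_times)) {
    bt <- first_times$time[match(ids, first_times$replica_id)]
    ord <- order(is.na(bt), bt, ids)
  } else ord <- order(ids)
  snaps <- list(); labels <- list(); blocks <- integer()
  for (tr in rset$trajectories[ord]) {
    fr <- seq(1L, tr$n_frames, by = max(1L, as.integer(round(stride / tr$dt))))
    blocks <- c(blocks, length(snaps) + 1L)
    for (k in fr) {
      p <- tr$coords[k, idx, , drop = FALSE]
      dim(p) <- c(length(idx), 3L)
      snaps[[length(snaps) + 1L]] <- p
      labels[[length(labels) + 1L]] <-
        data.frame(replica_id = tr$replica_id, time = tr$times[k])
    }
  }
  n <- length(snaps)
  if (n < 2L) stopf("rmsd_matrix: need at least 2 sampled frames")
  vals <- matrix(0, n, n)
  degen <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- pair_rmsd(snaps[[i]], snaps[[j]], mode)
      vals[i, j] <- vals[j, i] <- r$rmsd
      degen[i, j] <- degen[j, i] <- r$degenerate
    }
  }
  structure(list(values = vals, labels = do.call(rbind, labels),
                 order = ids[ord], blocks = blocks, degenerate = degen,
                 mode = mode, stride = stride),
            class = "RMSDMatrix")
}

pair_rmsd <- function(P, Q, mode) {
  if (mode == "global")
    return(list(rmsd = sqrt(mean(rowSums((P - Q)^2))), degenerate = FALSE))
  res <- tryCatch(kabsch(P, Q), error = function(e) NULL)
  if (is.null(res)) {
    ## degenerate (collinear or < 3 atoms): translate only, no rotation
    Pc <- sweep(P, 2L, colMeans(P)); Qc <- sweep(Q, 2L, colMeans(Q))
    list(rmsd = sqrt(mean(rowSums((Pc - Qc)^2))), degenerate = TRUE)
  } else list(rmsd = res$rmsd, degenerate = FALSE)
}

#' Write an RMSD matrix with its ordering sidecar
#'
#' Plain-text matrix (tab-separated, `replica:time` header labels) plus a
#' JSON sidecar holding the row ordering and replica block boundaries.
#'
#' @param m an `RMSDMatrix`
#' @param path output path for the matrix; the sidecar is
#'   `<path>.order.json`
#' @return `path`, invisibly
#' @export
write_rmsd_matrix <- function(m, path) {
  stopifnot(inherits(m, "RMSDMatrix"))
  lab <- sprintf("%d:%g", m$labels$replica_id, m$labels$time)
  df <- as.data.frame(m$values)
  names(df) <- lab
  utils::write.table(cbind(frame = lab, signif(df, 9)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(order = m$order, blocks = m$blocks,
                            mode = m$mode, stride = m$stride),
                       paste0(path, ".order.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
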