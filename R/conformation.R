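# Ensemble statistics over groove trajectories: superposition, RMSD series
# and distributions, per-residue RMSF, groove width variance, and leader
# clustering with its convergence diagnostic.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum |m R + t - r|^2` over the selected atoms, via SVD of the covariance
#' of the centered coordinate sets. The fitted coordinates are
#' `mobile %*% R + t` (row-vector convention).
#'
#' @param mobile,reference numeric `n x 3` coordinate matrices (Angstrom).
#' @param selection integer atom indices used for the fit (same indices in
#'   both sets); default all atoms.
#' @return list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3), and `rmsd` (Angstrom, over the selected atoms).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  m <- mobile[selection, , drop = FALSE]
  r <- reference[selection, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("selected atom counts differ between sets")
  if (nrow(m) < 3L) stop("degenerate selection: need >= 3 atoms")
  cm <- colMeans(m); cr <- colMeans(r)
  m0 <- sweep(m, 2L, cm); r0 <- sweep(r, 2L, cr)
  # collinearity check: centered coordinates must span a plane
  if (qr(m0)$rank < 2L || qr(r0)$rank < 2L)
    stop("degenerate selection: atoms are collinear")
  H <- crossprod(m0, r0)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tvec <- as.numeric(cr - cm %*% R)
  resid <- m0 %*% R - r0
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums(resid^2))))
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz `n x 3` matrix.
#' @param fit result of [superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2L, -fit$translation)
}

.plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Each frame is rigid-body fitted (by default) onto the reference over the
#' selection before the RMSD is taken, so the series is invariant to rigid
#' motions of the frames.
#'
#' @param traj a [groove_trajectory()].
#' @param reference reference coordinates: a [groove_structure()] or an
#'   `n x 3` matrix; default the trajectory's own reference structure (the
#'   crystal-derived starting geometry).
#' @param selection atom indices; default the groove C-alpha selection of the
#'   reference structure.
#' @param fit if `FALSE`, skip the superposition and report the plain
#'   coordinate RMSD over the selection.
#' @return object of class `rmsd_series`: list with `values` (Angstrom),
#'   `times` (ns), `selection`.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "groove_trajectory"))
  if (is.null(reference)) reference <- traj$reference
  ref_xyz <- if (inherits(reference, "groove_structure")) reference$xyz
             else as.matrix(reference)
  if (is.null(selection)) selection <- groove_selection(traj$reference)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    f <- frame_xyz(traj, i)
    if (fit) {
      tryCatch(superpose(f, ref_xyz, selection)$rmsd,
               error = function(e) stop(sprintf("frame %d: %s", i,
                                                conditionMessage(e)),
                                        call. = FALSE))
    } else {
      .plain_rmsd(f[selection, , drop = FALSE],
                  ref_xyz[selection, , drop = FALSE])
    }
  }, numeric(1))
  structure(list(values = vals, times = traj$times, selection = selection),
            class = "rmsd_series")
}

#' Normalized RMSD histogram with smoothed-density mode detection
#'
#' Pools one or several RMSD series into a probability histogram (bin
#' probabilities sum to 1) and reports the modes of a Gaussian kernel density
#' estimate: local maxima exceeding 5 percent of the global density maximum.
#'
#' @param series an `rmsd_series`, numeric vector, or list of either
#'   (pooled, "all trajectories").
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @param bandwidth kernel bandwidth; default Silverman's rule (`bw.nrd0`).
#' @param mode_threshold fraction of the global density maximum a local
#'   maximum must exceed to be called a mode (default 0.05).
#' @return object of class `rmsd_distribution`: `bin_centers`, `probability`,
#'   `density` (data frame x, y), `modes` (Angstrom).
#' @export
rmsd_distribution <- function(series, bin_width = 0.1, bandwidth = NULL,
                              mode_threshold = 0.05) {
  if (bin_width <= 0) stop("bin_width must be positive")
  pool <- function(s) {
    if (inherits(s, "rmsd_series")) s$values
    else if (is.list(s)) unlist(lapply(s, pool))
    else as.numeric(s)
  }
  v <- pool(series)
  if (length(v) < 10L) stop("need >= 10 RMSD values for a distribution")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < max(v)) breaks <- c(breaks, max(v) + bin_width)
  h <- hist(v, breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(v)
  # degenerate (constant) input: bw.nrd0 falls back to a tiny positive value
  if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- bin_width / 4
  den <- stats::density(v, bw = bandwidth)
  y <- den$y
  ny <- length(y)
  # local maxima, plateau-safe: last point of any flat top counts once
  is_max <- which(y >= c(-Inf, y[-ny]) & y > c(y[-1L], -Inf))
  modes <- den$x[is_max[y[is_max] > mode_threshold * max(y)]]
  structure(list(bin_centers = h$mids, probability = prob,
                 density = data.frame(x = den$x, y = y),
                 bandwidth = bandwidth, modes = modes),
            class = "rmsd_distribution")
}

#' Per-residue RMSF profile
#'
#' Frames are superposed onto the ensemble-average structure (one refit
#' iteration: fit all frames to the first frame, average, refit to the
#' average) and the root-mean-square fluctuation of each selected residue's
#' C-alpha about its ensemble mean is reported.
#'
#' @param traj a [groove_trajectory()].
#' @param selection atom indices to profile (default groove C-alpha).
#' @param superpose_selection atom indices used for the rigid fit (default
#'   same as `selection`).
#' @return object of class `rmsf_profile`: data frame `resno`, `rmsf`
#'   (Angstrom), ordered by residue number.
#' @export
rmsf_profile <- function(traj, selection = NULL, superpose_selection = NULL) {
  stopifnot(inherits(traj, "groove_trajectory"))
  if (is.null(selection)) selection <- groove_selection(traj$reference)
  if (is.null(superpose_selection)) superpose_selection <- selection
  nf <- n_frames(traj)
  if (nf < 2L) stop("undefined fluctuation: need >= 2 frames")
  fit_all <- function(target) {
    arr <- array(NA_real_, dim = dim(traj$coords))
    for (i in seq_len(nf)) {
      f <- frame_xyz(traj, i)
      ft <- superpose(f, target, superpose_selection)
      arr[, , i] <- apply_transform(f, ft)
    }
    arr
  }
  a1 <- fit_all(frame_xyz(traj, 1L))
  mean1 <- apply(a1, c(1L, 2L), mean)
  a2 <- fit_all(mean1)
  mean2 <- apply(a2, c(1L, 2L), mean)
  dev2 <- sweep(a2, c(1L, 2L), mean2)
  msf <- rowMeans(apply(dev2, 3L, function(f) rowSums(f^2)))
  resno <- traj$reference$atom$resno[selection]
  ord <- order(resno)
  structure(data.frame(resno = resno[ord],
                       rmsf = sqrt(msf[selection])[ord]),
            class = c("rmsf_profile", "data.frame"))
}

#' Groove width variance over a helix region
#'
#' The per-frame width is the Euclidean distance between the unweighted
#' C-alpha centroids of the region's two opposing helix segments, computed
#' without any superposition (inter-atomic distances are rotation invariant).
#' The width variance (WV) is the population variance (divide by n) of the
#' width series, in Angstrom squared.
#'
#' @param traj a [groove_trajectory()].
#' @param region a [region_definition()] or a region name `"I"`/`"II"`/`"III"`.
#' @return object of class `width_variance`: list with `region`, `widths`
#'   (per-frame, Angstrom), `mean_width`, `wv` (Angstrom^2).
#' @export
width_variance <- function(traj, region) {
  stopifnot(inherits(traj, "groove_trajectory"))
  if (is.character(region)) region <- region_definition(region)
  ref <- traj$reference
  sel_a <- tryCatch(select_atoms(ref, elety = "CA", resno = region$helix_a),
                    error = function(e) stop("structural mismatch in segment a: ",
                                             conditionMessage(e), call. = FALSE))
  sel_b <- tryCatch(select_atoms(ref, elety = "CA", resno = region$helix_b),
                    error = function(e) stop("structural mismatch in segment b: ",
                                             conditionMessage(e), call. = FALSE))
  nf <- n_frames(traj)
  widths <- vapply(seq_len(nf), function(i) {
    f <- frame_xyz(traj, i)
    ca <- colMeans(f[sel_a, , drop = FALSE])
    cb <- colMeans(f[sel_b, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  mu <- mean(widths)
  structure(list(region = region$name, widths = widths, mean_width = mu,
                 wv = mean((widths - mu)^2)),
            class = "width_variance")
}

#' Single-pass leader clustering of trajectory frames
#'
#' Frames are scanned in order; a frame joins the first existing cluster whose
#' representative (founding frame) is within the RMSD cutoff after
#' superposition, otherwise it founds a new cluster. Deterministic given the
#' frame order.
#'
#' @param traj a [groove_trajectory()].
#' @param selection atom indices for the RMSD (default groove C-alpha).
#' @param cutoff RMSD cutoff in Angstrom (default 1.5).
#' @return object of class `cluster_assignment`: `labels` (per frame,
#'   contiguous from 1), `representatives` (frame indices), `cutoff`.
#' @export
cluster_leader <- function(traj, selection = NULL, cutoff = 1.5) {
  stopifnot(inherits(traj, "groove_trajectory"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(selection)) selection <- groove_selection(traj$reference)
  nf <- n_frames(traj)
  labels <- integer(nf)
  reps <- integer(0)
  rep_xyz <- list()
  for (i in seq_len(nf)) {
    f <- frame_xyz(traj, i)
    assigned <- FALSE
    for (c in seq_along(reps)) {
      if (superpose(f, rep_xyz[[c]], selection)$rmsd <= cutoff) {
        labels[i] <- c; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rep_xyz[[length(reps)]] <- f
      labels[i] <- length(reps)
    }
  }
  structure(list(labels = labels, representatives = reps, cutoff = cutoff),
            class = "cluster_assignment")
}

#' Cluster-count convergence diagnostic
#'
#' Number of leader clusters as a function of cumulative simulation time:
#' at each checkpoint the count equals the cluster count of the prefix
#' trajectory (leader clustering is incremental, so a single pass suffices).
#' The series is non-decreasing by construction.
#'
#' @param traj a [groove_trajectory()].
#' @param selection atom indices (default groove C-alpha).
#' @param cutoff RMSD cutoff in Angstrom.
#' @param checkpoints increasing frame counts at which to report.
#' @return data frame with `frames`, `time` (ns), `n_clusters`.
#' @export
cluster_convergence <- function(traj, selection = NULL, cutoff = 1.5,
                                checkpoints) {
  stopifnot(inherits(traj, "groove_trajectory"))
  checkpoints <- as.integer(checkpoints)
  if (any(diff(checkpoints) <= 0)) stop("checkpoints must be increasing")
  if (max(checkpoints) > n_frames(traj))
    stop("checkpoint beyond trajectory length")
  cl <- cluster_leader(traj, selection = selection, cutoff = cutoff)
  n_at <- vapply(checkpoints, function(k) sum(cl$representatives <= k), 1L)
  data.frame(frames = checkpoints, time = traj$times[checkpoints],
             n_clusters = n_at)
}
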