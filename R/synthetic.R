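# Synthetic-data generators with known ground truth for every input the
# pipeline consumes: a toy binding-groove trajectory with region-dependent
# width fluctuations, Metropolis-sampled umbrella windows on a declared 1-D
# potential, Gaussian energy-component tables with cluster structure, and
# noisy melting / competition / decay curves. Every generator is a pure
# function of its configuration including the mandatory seed.

.ou_series <- function(n, sd, tau) {
  # stationary Ornstein-Uhlenbeck (AR(1)) series with stationary SD `sd` and
  # correlation time `tau` frames
  if (sd == 0) return(rep(0, n))
  rho <- exp(-1 / tau)
  w <- numeric(n)
  w[1L] <- stats::rnorm(1L, 0, sd)
  innov <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - rho^2))
  for (i in 2L:n) w[i] <- rho * w[i - 1L] + innov[i - 1L]
  w
}

#' Idealized toy binding-groove structure
#'
#' A C-alpha-only stand-in for the alpha1/alpha2 superdomain: the two
#' helix stretches that carry the region segments (residues 50-84 and
#' 139-176) run antiparallel 10 Angstrom apart above a flat sheet holding
#' the remaining residues. The geometry is deliberately schematic - the
#' pipeline depends only on the declared residue regions, not on realistic
#' coordinates.
#'
#' @param n_residues number of residues (default 180, the groove scope).
#' @param separation helix-helix distance in Angstrom (default 10).
#' @return a [groove_structure()] with one CA atom per residue, chain A.
#' @export
toy_groove_structure <- function(n_residues = 180, separation = 10) {
  stopifnot(n_residues >= 1)
  res <- seq_len(n_residues)
  xyz <- matrix(0, n_residues, 3L)
  helix_a <- res >= 50 & res <= 84
  helix_b <- res >= 139 & res <= 176
  sheet <- !(helix_a | helix_b)
  xyz[helix_a, 1L] <- (res[helix_a] - 50) * 1.5
  xyz[helix_a, 2L] <- separation / 2
  xyz[helix_a, 3L] <- 5
  xyz[helix_b, 1L] <- (176 - res[helix_b]) * 1.5
  xyz[helix_b, 2L] <- -separation / 2
  xyz[helix_b, 3L] <- 5
  ns <- sum(sheet)
  xyz[sheet, 1L] <- rep(seq_len(ceiling(ns / 8)), each = 8L, length.out = ns) * 3.5
  xyz[sheet, 2L] <- rep(seq_len(8L) - 4.5, length.out = ns) * 3.5
  xyz[sheet, 3L] <- 0
  groove_structure(data.frame(
    eleno = res, elety = "CA", resid = "ALA", chain = "A", resno = res,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], b = 0,
    stringsAsFactors = FALSE))
}

#' Generate a toy groove trajectory with configured region flexibility
#'
#' Each region's two helix segments are displaced in opposite directions
#' along the reference axis joining their C-alpha centroids by half of an
#' Ornstein-Uhlenbeck width fluctuation with stationary SD `sd_width[region]`
#' and correlation time `tau` frames, so the centroid-to-centroid width of
#' region r has SD exactly `sd_width[r]` (up to jitter). Isotropic Gaussian
#' jitter of SD `jitter_sd` is added per atom and coordinate. This emulates
#' the empty >> C-truncated >> full-length flexibility contrast of the
#' F-pocket region while the A-pocket region stays near-constant.
#'
#' @param n_frames number of frames.
#' @param sd_width named numeric: stationary width SD (Angstrom) per region
#'   `I`, `II`, `III`.
#' @param jitter_sd per-residue isotropic positional jitter SD (Angstrom).
#' @param tau OU correlation time in frames (default 20).
#' @param seed mandatory RNG seed.
#' @param reference optional [groove_structure()]; default [toy_groove_structure()].
#' @param dt frame spacing in ns (default 0.1).
#' @return list with `structure` and `trajectory` (a [groove_trajectory()]).
#' @export
gen_groove_trajectory <- function(n_frames,
                                  sd_width = c(I = 0.3, II = 0.3, III = 0.3),
                                  jitter_sd = 0.1, tau = 20, seed,
                                  reference = NULL, dt = 0.1) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (any(sd_width < 0) || jitter_sd < 0) stop("SDs must be >= 0")
  if (is.null(reference)) reference <- toy_groove_structure()
  regions <- lapply(c("I", "II", "III"), region_definition)
  names(regions) <- c("I", "II", "III")
  sdw <- c(I = 0, II = 0, III = 0)
  sdw[names(sd_width)] <- sd_width
  n_atoms <- nrow(reference$xyz)
  .with_seed(seed, {
    arr <- array(rep(reference$xyz, n_frames),
                 dim = c(n_atoms, 3L, n_frames))
    for (rn in names(regions)) {
      reg <- regions[[rn]]
      sel_a <- select_atoms(reference, elety = "CA", resno = reg$helix_a)
      sel_b <- select_atoms(reference, elety = "CA", resno = reg$helix_b)
      axis <- colMeans(reference$xyz[sel_b, , drop = FALSE]) -
        colMeans(reference$xyz[sel_a, , drop = FALSE])
      d0 <- sqrt(sum(axis^2))
      axis <- axis / d0
      w <- .ou_series(n_frames, sdw[[rn]], tau)
      if (any(d0 + w <= 0.5))
        warning(sprintf("region %s width SD so large that segments overlap", rn))
      for (d in 1:3) {
        arr[sel_a, d, ] <- sweep(arr[sel_a, d, ], 2L, axis[d] * w / 2, "-")
        arr[sel_b, d, ] <- sweep(arr[sel_b, d, ], 2L, axis[d] * w / 2, "+")
      }
    }
    if (jitter_sd > 0)
      arr <- arr + array(stats::rnorm(length(arr), 0, jitter_sd), dim = dim(arr))
    list(structure = reference,
         trajectory = groove_trajectory(arr, times = seq_len(n_frames) * dt,
                                        reference = reference))
  })
}

#' Metropolis-sampled umbrella windows on a declared 1-D potential
#'
#' For each bias center, samples the reaction coordinate xi from the
#' Boltzmann distribution of `U(xi) + k/2 (xi - center)^2` at the given
#' temperature with a symmetric Gaussian-step Metropolis chain; the first
#' `burn_in` fraction of each chain is discarded. Exact stationary
#' distribution, trivially verifiable against closed forms.
#'
#' @param potential function `U(xi)` in kcal/mol.
#' @param centers bias centers xi_0 (Angstrom).
#' @param k harmonic force constant(s), kcal/mol/Angstrom^2 (recycled).
#' @param n_steps Metropolis steps per window (post burn-in count is
#'   `n_steps * (1 - burn_in)`).
#' @param step_size proposal SD in Angstrom (default 0.3).
#' @param temperature K (default 300).
#' @param burn_in fraction discarded (default 0.1).
#' @param seed mandatory RNG seed.
#' @return an [umbrella_window_set()]; a warning is raised if any window's
#'   acceptance rate falls below 5 percent.
#' @export
gen_umbrella_windows <- function(potential, centers, k, n_steps,
                                 step_size = 0.3, temperature = 300,
                                 burn_in = 0.1, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  k <- rep_len(k, length(centers))
  beta <- 1 / (KB_KCAL * temperature)
  .with_seed(seed, {
    windows <- vector("list", length(centers))
    for (j in seq_along(centers)) {
      u_tot <- function(x) potential(x) + 0.5 * k[j] * (x - centers[j])^2
      x <- centers[j]
      e <- u_tot(x)
      xs <- numeric(n_steps)
      acc <- 0L
      prop <- stats::rnorm(n_steps, 0, step_size)
      unif <- stats::runif(n_steps)
      for (i in seq_len(n_steps)) {
        xn <- x + prop[i]
        en <- u_tot(xn)
        if (unif[i] < exp(-beta * (en - e))) { x <- xn; e <- en; acc <- acc + 1L }
        xs[i] <- x
      }
      if (acc / n_steps < 0.05)
        warning(sprintf("window %d: Metropolis acceptance %.1f%% < 5%% - reduce step_size",
                        j, 100 * acc / n_steps))
      keep <- seq.int(floor(burn_in * n_steps) + 1L, n_steps)
      windows[[j]] <- list(center = centers[j], k = k[j], samples = xs[keep])
    }
    umbrella_window_set(windows, temperature = temperature)
  })
}

#' Symmetric double-well potential
#'
#' `U(xi) = h ((( xi - c ) / w)^2 - 1)^2`: minima at `c - w` and `c + w`,
#' barrier of height `h` at `xi = c`. A stand-in dissociation profile for
#' exercising the umbrella-sampling / WHAM route.
#'
#' @param h barrier height, kcal/mol.
#' @param c barrier position (Angstrom).
#' @param w half-distance between the minima (Angstrom).
#' @return function `U(xi)`.
#' @export
double_well_potential <- function(h = 4, c = 2.75, w = 1.75) {
  force(h); force(c); force(w)
  function(xi) h * (((xi - c) / w)^2 - 1)^2
}

#' Generate a per-frame energy-component table with cluster structure
#'
#' Per-frame energy terms are Gaussian around the configured per-system
#' means; frames are assigned to `n_clusters` contiguous equal blocks, and
#' `cluster_offsets[c]` is added to the complex rows' `E_vdw` term of cluster
#' c, so the ground-truth binding free energy of cluster c is
#' `dG0 + cluster_offsets[c]` with
#' `dG0 = sum(means[complex,]) - sum(means[receptor,]) - sum(means[ligand,])`.
#'
#' @param means 3 x 5 numeric matrix (rows `complex`, `receptor`, `ligand`;
#'   columns the five energy components) of per-frame term means, kcal/mol.
#' @param sds like `means`, per-term Gaussian SDs (a scalar is recycled).
#' @param n_frames number of frames.
#' @param n_clusters number of contiguous frame clusters (default 1).
#' @param cluster_offsets numeric of length `n_clusters` (default all 0).
#' @param seed mandatory RNG seed.
#' @return an [energy_frame_table()] with attribute `truth` (list with `dG0`
#'   and `cluster_dG`).
#' @export
gen_energy_tables <- function(means, sds = 0, n_frames, n_clusters = 1,
                              cluster_offsets = numeric(n_clusters), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  means <- as.matrix(means)
  if (is.null(rownames(means))) rownames(means) <- SYSTEMS
  if (is.null(colnames(means))) colnames(means) <- ENERGY_TERMS
  if (length(sds) == 1L) sds <- matrix(sds, 3L, 5L, dimnames = dimnames(means))
  if (length(cluster_offsets) != n_clusters)
    stop("cluster_offsets must have length n_clusters")
  cl <- rep(seq_len(n_clusters), each = ceiling(n_frames / n_clusters),
            length.out = n_frames)
  .with_seed(seed, {
    rows <- lapply(SYSTEMS, function(s) {
      e <- vapply(ENERGY_TERMS, function(term)
        stats::rnorm(n_frames, means[s, term], sds[s, term]), numeric(n_frames))
      e <- matrix(e, nrow = n_frames,
                  dimnames = list(NULL, ENERGY_TERMS))
      if (s == "complex") e[, "E_vdw"] <- e[, "E_vdw"] + cluster_offsets[cl]
      data.frame(system = s, frame = seq_len(n_frames), cluster = cl, e,
                 stringsAsFactors = FALSE)
    })
    tab <- energy_frame_table(do.call(rbind, rows))
    dG0 <- sum(means["complex", ]) - sum(means["receptor", ]) - sum(means["ligand", ])
    attr(tab, "truth") <- list(dG0 = dG0, cluster_dG = dG0 + cluster_offsets)
    tab
  })
}

#' Generate a noisy measurement curve with known parameters
#'
#' Families: `"melting"` (two-state denaturation, params `Tm` K, `dHm`,
#' `a_n`, `b_n`, `a_u`, `b_u`, optional `dCp`), `"competition"`
#' (four-parameter logistic, params `ic50` M, `h`, `a_lo`, `a_hi`) and
#' `"decay"` (exponential surface decay, params `k` 1/min, `n_inf` percent).
#' Homoscedastic Gaussian noise of SD `noise_sd` is added; the true
#' parameters are attached as attribute `truth`.
#'
#' @param family model family.
#' @param params named list of true parameters (see above).
#' @param x x grid: temperatures (K), concentrations (M) or times (min).
#' @param noise_sd Gaussian noise SD in response units (default 0).
#' @param seed mandatory RNG seed.
#' @return a [curve_table()] with attribute `truth`.
#' @export
gen_curve <- function(family = c("melting", "competition", "decay"),
                      params, x, noise_sd = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  family <- match.arg(family)
  y0 <- switch(family,
    melting = .melting_model(x, params$Tm, params$dHm, params$a_n, params$b_n,
                             params$a_u, params$b_u, dCp = params$dCp %||% 0),
    competition = .logistic4(x, params$ic50, params$h, params$a_lo, params$a_hi),
    decay = .decay_model(x, params$k, params$n_inf))
  unit <- switch(family, melting = "K", competition = "M", decay = "min")
  .with_seed(seed, {
    y <- y0 + stats::rnorm(length(x), 0, noise_sd)
    out <- curve_table(x, y, x_unit = unit)
    attr(out, "truth") <- c(params, list(family = family, noise_sd = noise_sd,
                                         seed = seed))
    out
  })
}
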