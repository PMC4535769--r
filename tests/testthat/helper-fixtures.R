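# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive reimplementations kept separate from the package code
# paths they check.

# -- tiny PDB fixtures --------------------------------------------------------

toy_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00",
    "ATOM      3  C   ALA A   1      10.759   5.242  -4.229  1.00  0.00")
}

# n-residue CA-only structure at given coordinates (one atom per residue)
ca_structure <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A") {
  groove_structure(data.frame(
    eleno = seq_len(nrow(xyz)), elety = "CA", resid = "GLY",
    chain = chain, resno = resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0))
}

# trajectory from a list of coordinate matrices over a CA structure
ca_trajectory <- function(frames, resno = seq_len(nrow(frames[[1]]))) {
  ref <- ca_structure(frames[[1]], resno = resno)
  groove_trajectory(frames, times = seq_along(frames), reference = ref)
}

# non-degenerate 10-atom cloud (fixed, well-conditioned)
cloud10 <- function() {
  matrix(c(0,0,0, 3,0,0, 0,3,0, 0,0,3, 3,3,0, 3,0,3, 0,3,3, 3,3,3,
           1.5,1.5,0, 1.5,0,1.5), ncol = 3, byrow = TRUE)
}

# -- rigid motions ------------------------------------------------------------

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% R, 2, -t)

rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# -- independent oracles ------------------------------------------------------

euler_rot <- function(a, b, g) {
  rotz(a * 180 / pi) %*%
    matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE) %*%
    rotz(g * 180 / pi)
}

# brute-force best-fit RMSD: exhaustive Euler-angle grid, then local
# refinement; translation handled by centroid alignment (optimal for any
# fixed rotation)
grid_rmsd_oracle <- function(mobile, reference, grid_deg = 6) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  rmsd_of <- function(ang) {
    Q <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((m0 %*% Q - r0)^2)))
  }
  step <- grid_deg * pi / 180
  best <- c(0, 0, 0); best_v <- rmsd_of(best)
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step / 2, by = step)) {
        v <- rmsd_of(c(a, b, g))
        if (v < best_v) { best_v <- v; best <- c(a, b, g) }
      }
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# frame-by-frame naive leader clustering, independent loop over a supplied
# pairwise-RMSD function
naive_leader <- function(traj, selection, cutoff, rmsd_fun) {
  nf <- dim(traj$coords)[3]
  labels <- integer(nf); reps <- integer(0)
  for (i in seq_len(nf)) {
    f <- traj$coords[, , i]
    hit <- 0L
    for (ci in seq_along(reps)) {
      if (rmsd_fun(f, traj$coords[, , reps[ci]], selection) <= cutoff) {
        hit <- ci; break
      }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    labels[i] <- hit
  }
  list(labels = labels, representatives = reps)
}

# two-pass SD over cluster means of per-frame dG, computed straight from the
# raw table without touching mmpbsa_aggregate internals
naive_cluster_sd <- function(table) {
  terms <- c("E_internal", "E_vdw", "E_elec", "G_polar", "G_nonpolar")
  g <- function(s) {
    sub <- table[table$system == s, ]
    sub <- sub[order(sub$frame), ]
    rowSums(as.matrix(sub[, terms]))
  }
  dg <- g("complex") - g("receptor") - g("ligand")
  cl <- table[table$system == "complex", ]
  cl <- cl$cluster[order(cl$frame)]
  means <- vapply(sort(unique(cl)), function(c) mean(dg[cl == c]), numeric(1))
  mu <- sum(means) / length(means)
  sqrt(sum((means - mu)^2) / (length(means) - 1))
}

# naive, scalar-loop WHAM used as an independent reference implementation
naive_wham <- function(windows, temperature, bin_width, tol = 1e-10,
                       maxit = 2e5) {
  kB <- 0.0019872041
  beta <- 1 / (kB * temperature)
  all_xi <- unlist(lapply(windows, function(w) w$samples))
  lo <- floor(min(all_xi) / bin_width) * bin_width
  hi <- ceiling(max(all_xi) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  J <- length(windows); B <- length(centers)
  n <- matrix(0, J, B)
  for (j in seq_len(J))
    for (s in windows[[j]]$samples) {
      b <- min(max(floor((s - lo) / bin_width) + 1, 1), B)
      n[j, b] <- n[j, b] + 1
    }
  N <- rowSums(n)
  cjb <- matrix(0, J, B)
  for (j in seq_len(J))
    cjb[j, ] <- exp(-beta * 0.5 * windows[[j]]$k *
                      (centers - windows[[j]]$center)^2)
  F <- rep(1, J)  # exp(beta f_j)
  for (it in seq_len(maxit)) {
    P <- numeric(B)
    for (b in seq_len(B)) {
      den <- 0
      for (j in seq_len(J)) den <- den + N[j] * F[j] * cjb[j, b]
      P[b] <- if (den > 0) sum(n[, b]) / den else 0
    }
    Fn <- numeric(J)
    for (j in seq_len(J)) Fn[j] <- 1 / sum(cjb[j, ] * P)
    Fn <- Fn / Fn[1]
    if (max(abs(log(Fn) - log(F))) < beta * tol) { F <- Fn; break }
    F <- Fn
  }
  W <- -log(P) / beta
  W[P == 0] <- NA
  list(xi = centers, W = W - min(W, na.rm = TRUE))
}

# dual-route synthetic variant study: per variant, a ground-truth binding
# destabilization ddg_true drives both an energy table (MM-PBSA route) and a
# melting curve (TDTF route, Tm shifted by the inverse two-state relation)
make_variant_study <- function(ddg_true, seed, Tm_ref = 328.85, dHm = 120,
                               dG_ref = -45, noise_energy = 1.5,
                               noise_fluor = 1.0) {
  variants <- names(ddg_true)
  base <- matrix(c(-300, -80, -40, -120, -10,
                   -220, -50, -20, -100, -8,
                   -35, -15, -5, -15, -2), 3, 5, byrow = TRUE,
                 dimnames = list(c("complex", "receptor", "ligand"),
                                 c("E_internal", "E_vdw", "E_elec",
                                   "G_polar", "G_nonpolar")))
  # shift the complex electrostatics so that dG0 = dG_ref + ddg_true
  dg_base <- sum(base[1, ]) - sum(base[2, ]) - sum(base[3, ])
  mm <- list(); td <- list()
  for (i in seq_along(variants)) {
    v <- variants[i]
    m <- base
    m["complex", "E_elec"] <- m["complex", "E_elec"] +
      (dG_ref + ddg_true[[v]] - dg_base)
    tab <- gen_energy_tables(m, sds = noise_energy, n_frames = 60,
                             n_clusters = 4, seed = seed + i)
    mm[[v]] <- mmpbsa_aggregate(tab)
    # TDTF route: destabilization lowers Tm by ddg * Tm_ref / dHm
    Tm_v <- Tm_ref - ddg_true[[v]] * Tm_ref / dHm
    cv <- gen_curve("melting",
                    list(Tm = Tm_v, dHm = dHm, a_n = 100, b_n = -0.12,
                         a_u = 35, b_u = -0.05),
                    x = seq(283, 363, by = 1), noise_sd = noise_fluor,
                    seed = seed + 100 + i)
    td[[v]] <- fit_melting_curve(cv)
  }
  ref <- variants[1]
  mm_ddg <- vapply(mm, function(r) r$dG - mm[[ref]]$dG, numeric(1))
  td_ddg <- vapply(variants, function(v)
    ddg_from_tm(td[[v]], td[[ref]])$ddG, numeric(1))
  names(mm_ddg) <- variants; names(td_ddg) <- variants
  list(mmpbsa = mm_ddg, tdtf = td_ddg, fits_mm = mm, fits_td = td)
}
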