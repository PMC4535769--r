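test_that("superposition removes rigid motions and returns a proper rotation", {
  m <- cloud10()
  f <- superpose(m, m)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
  moved <- apply_rigid(m, rotz(90), c(1, 2, 3))
  f2 <- superpose(moved, m)
  expect_lt(f2$rmsd, 1e-10)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_transform(moved, f2), m, tolerance = 1e-9)
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(cloud10()[1:2, ], cloud10()[1:2, ]), ">= 3")
})

test_that("best-fit RMSD of a displaced-vertex set matches the rotation-grid oracle", {
  ref <- matrix(c(0, 0, 0, 2, 0, 0, 2, 2, 0, 0, 2, 0), ncol = 3, byrow = TRUE)
  mob <- ref
  mob[3, 3] <- 1  # one vertex pushed 1 A out of plane
  set.seed(11)
  mob <- apply_rigid(mob, random_rotation(), c(0.3, -0.8, 1.1))
  expect_equal(superpose(mob, ref)$rmsd, grid_rmsd_oracle(mob, ref, grid_deg = 10),
               tolerance = 1e-3)
})

test_that("rmsd_series is invariant to per-frame rigid motions", {
  set.seed(21)
  ref <- ca_structure(cloud10())
  frames <- lapply(1:8, function(i)
    apply_rigid(cloud10(), random_rotation(), rnorm(3, 0, 5)))
  tr <- groove_trajectory(frames, times = 1:8, reference = ref)
  rs <- rmsd_series(tr, selection = 1:10)
  expect_lt(max(rs$values), 1e-8)
})

test_that("rmsd_series equals independent per-frame fits; plain RMSD has its closed form", {
  set.seed(22)
  ref <- ca_structure(cloud10())
  frames <- lapply(1:5, function(i) cloud10() + matrix(rnorm(30, 0, 0.4), 10, 3))
  tr <- groove_trajectory(frames, times = 1:5, reference = ref)
  rs <- rmsd_series(tr, selection = 1:10)
  oracle <- vapply(frames, function(f) superpose(f, cloud10())$rmsd, numeric(1))
  expect_equal(rs$values, oracle, tolerance = 1e-12)

  # one atom displaced 2 A in one frame of a 10-atom selection: plain
  # (unfitted) RMSD is exactly 2/sqrt(10)
  f2 <- cloud10(); f2[4, 1] <- f2[4, 1] + 2
  tr2 <- groove_trajectory(list(cloud10(), f2), times = 1:2, reference = ref)
  rs2 <- rmsd_series(tr2, selection = 1:10, fit = FALSE)
  expect_equal(rs2$values, c(0, 2 / sqrt(10)), tolerance = 1e-12)
})

test_that("rmsd_distribution normalizes, finds modes, and enforces minimum n", {
  d <- rmsd_distribution(rep(2.2, 50), bin_width = 0.1)
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)
  expect_equal(length(d$modes), 1L)
  expect_lt(abs(d$modes - 2.2), 0.05)

  set.seed(31)
  v <- c(rnorm(5000, 2.5, 0.05), rnorm(5000, 3.0, 0.05))
  d2 <- rmsd_distribution(v, bin_width = 0.1)
  expect_equal(length(d2$modes), 2L)
  expect_lt(abs(d2$modes[1] - 2.5), 0.05)
  expect_lt(abs(d2$modes[2] - 3.0), 0.05)

  expect_error(rmsd_distribution(rnorm(5)), ">= 10")
  expect_error(rmsd_distribution(rep(2, 20), bin_width = 0), "positive")
})

test_that("rmsd_distribution pools multiple series", {
  s1 <- structure(list(values = rep(1, 20)), class = "rmsd_series")
  s2 <- structure(list(values = rep(3, 20)), class = "rmsd_series")
  d <- rmsd_distribution(list(s1, s2), bin_width = 0.5)
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)
  expect_equal(length(d$modes), 2L)
})

test_that("RMSF is zero for static ensembles and exact for anchored oscillation", {
  xyz <- rbind(cloud10() * 3, c(50, 0, 0))  # big rigid anchor + one mobile atom
  ref <- ca_structure(xyz)
  static <- groove_trajectory(list(xyz, xyz, xyz), times = 1:3, reference = ref)
  p0 <- rmsf_profile(static, selection = 1:11, superpose_selection = 1:10)
  expect_true(all(p0$rmsf == 0))

  delta <- 0.7
  up <- xyz; up[11, 1] <- 50 + delta
  dn <- xyz; dn[11, 1] <- 50 - delta
  tr <- groove_trajectory(list(up, dn, up, dn), times = 1:4, reference = ref)
  p <- rmsf_profile(tr, selection = 1:11, superpose_selection = 1:10)
  expect_equal(p$rmsf[p$resno == 11], delta, tolerance = 1e-9)
  expect_error(rmsf_profile(groove_trajectory(list(xyz), times = 1,
                                              reference = ref)), ">= 2 frames")
})

test_that("RMSF of isotropic Gaussian jitter converges to sigma*sqrt(3)", {
  set.seed(41)
  xyz <- rbind(cloud10() * 10, matrix(rnorm(60, 0, 8), 20, 3))
  ref <- ca_structure(xyz)
  sigma <- 0.2
  nf <- 4000
  arr <- array(rep(xyz, nf), dim = c(30, 3, nf))
  arr[11:30, , ] <- arr[11:30, , ] + rnorm(20 * 3 * nf, 0, sigma)
  tr <- groove_trajectory(arr, times = 1:nf, reference = ref)
  p <- rmsf_profile(tr, selection = 11:30, superpose_selection = 1:10)
  expect_equal(mean(p$rmsf), sigma * sqrt(3), tolerance = 0.02)
})

test_that("RMSF profile order follows residue number regardless of atom order", {
  xyz <- rbind(cloud10() * 3, c(50, 0, 0), c(0, 50, 0))
  ref <- ca_structure(xyz, resno = c(1:10, 20, 12))  # out-of-order residues
  set.seed(42)
  frames <- lapply(1:6, function(i) xyz + rnorm(36, 0, 0.1))
  tr <- groove_trajectory(frames, times = 1:6, reference = ref)
  p <- rmsf_profile(tr, selection = 1:12, superpose_selection = 1:10)
  expect_equal(p$resno, sort(c(1:10, 20, 12)))
  expect_true(all(p$rmsf >= 0))
})

test_that("width variance: rigid zero, alternating 9/11 gives exactly 1.0 A^2", {
  reg <- region_definition("I", helix_a = 1:3, helix_b = 4:6)
  base <- function(d) rbind(cbind(c(-1, 0, 1), 0, 0), cbind(c(-1, 0, 1), d, 0))
  rigid <- ca_trajectory(list(base(10), base(10), base(10)))
  expect_equal(width_variance(rigid, reg)$wv, 0)

  alt <- ca_trajectory(list(base(9), base(11), base(9), base(11)))
  res <- width_variance(alt, reg)
  expect_equal(res$wv, 1.0, tolerance = 1e-12)
  expect_equal(res$mean_width, 10)
  expect_error(width_variance(rigid, region_definition("I", helix_a = 1:3,
                                                       helix_b = 7:9)),
               "structural mismatch")
})

test_that("width variance is unchanged by per-frame rigid motions", {
  set.seed(51)
  g <- gen_groove_trajectory(n_frames = 60, sd_width = c(I = 0.4, III = 0.9),
                             jitter_sd = 0.05, seed = 8)
  tr <- g$trajectory
  wv0 <- width_variance(tr, "III")$wv
  arr <- tr$coords
  for (i in seq_len(dim(arr)[3]))
    arr[, , i] <- apply_rigid(arr[, , i], random_rotation(), rnorm(3, 0, 10))
  tr2 <- groove_trajectory(arr, times = tr$times, reference = tr$reference)
  expect_lt(abs(width_variance(tr2, "III")$wv - wv0), 1e-10)
})

test_that("leader clustering matches trivial cases and the naive oracle", {
  f <- cloud10()
  tr <- ca_trajectory(list(f, f, f, f))
  cl <- cluster_leader(tr, selection = 1:10, cutoff = 0.5)
  expect_equal(length(cl$representatives), 1L)
  expect_equal(cl$labels, rep(1L, 4))

  # two conformer groups with inter-group best-fit RMSD ~3 A
  g2 <- f + matrix(rep(c(3 * sqrt(10) / sqrt(10), 0, 0), each = 10), 10, 3)
  g2[, 1] <- f[, 1] + c(rep(4.4, 5), rep(-4.4, 5))  # non-rigid deformation
  tr2 <- ca_trajectory(list(f, g2, f, g2))
  d <- superpose(g2, f)$rmsd
  expect_gt(d, 2.5)
  cl2 <- cluster_leader(tr2, selection = 1:10, cutoff = 1.5)
  expect_equal(length(cl2$representatives), 2L)
  expect_equal(cl2$labels, c(1L, 2L, 1L, 2L))

  set.seed(61)
  frames <- lapply(1:30, function(i) cloud10() + matrix(rnorm(30, 0, 0.8), 10, 3))
  tr3 <- ca_trajectory(frames)
  for (cutoff in c(0.4, 0.9, 100)) {
    got <- cluster_leader(tr3, selection = 1:10, cutoff = cutoff)
    ora <- naive_leader(tr3, 1:10, cutoff,
                        function(a, b, s) superpose(a, b, s)$rmsd)
    expect_equal(got$labels, ora$labels)
    expect_equal(got$representatives, ora$representatives)
  }
  # one cluster when cutoff exceeds every pairwise RMSD
  expect_equal(length(cluster_leader(tr3, selection = 1:10,
                                     cutoff = 100)$representatives), 1L)
})

test_that("cluster count is non-increasing in cutoff", {
  set.seed(62)
  frames <- lapply(1:25, function(i) cloud10() + matrix(rnorm(30, 0, 1), 10, 3))
  tr <- ca_trajectory(frames)
  ns <- vapply(c(0.3, 0.6, 1.2, 2.4), function(ct)
    length(cluster_leader(tr, selection = 1:10, cutoff = ct)$representatives),
    1L)
  expect_true(all(diff(ns) <= 0))
})

test_that("cluster convergence curve is prefix-consistent and plateaus", {
  f <- cloud10()
  shift <- function(d) f + matrix(rep(c(d, 0, 0), each = 10) *
                                    rep(c(1, -1), 5), 10, 3)
  confs <- list(f, shift(4), shift(8))  # three distinct conformers
  frames <- confs[c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)]
  tr <- ca_trajectory(frames)
  cc <- cluster_convergence(tr, selection = 1:10, cutoff = 1.0,
                            checkpoints = c(2, 3, 6, 10))
  expect_true(all(diff(cc$n_clusters) >= 0))
  expect_equal(cc$n_clusters[2], 3L)
  expect_equal(cc$n_clusters[4], 3L)
  # prefix identity at every checkpoint
  for (r in seq_len(nrow(cc))) {
    k <- cc$frames[r]
    sub <- groove_trajectory(tr$coords[, , 1:k, drop = FALSE],
                             times = tr$times[1:k], reference = tr$reference)
    expect_equal(cc$n_clusters[r],
                 length(cluster_leader(sub, selection = 1:10,
                                       cutoff = 1.0)$representatives))
  }
  expect_error(cluster_convergence(tr, selection = 1:10, cutoff = 1,
                                   checkpoints = c(5, 20)), "beyond")

  static <- ca_trajectory(list(f, f, f, f))
  cs <- cluster_convergence(static, selection = 1:10, cutoff = 1,
                            checkpoints = c(1, 2, 4))
  expect_true(all(cs$n_clusters == 1L))
})

test_that("superposition agrees with an established structural-biology fit", {
  set.seed(71)
  a <- cloud10() + matrix(rnorm(30, 0, 0.3), 10, 3)
  b <- apply_rigid(cloud10(), random_rotation(), c(2, -1, 4))
  ours <- superpose(b, a)$rmsd
  xyz_a <- as.vector(t(a)); xyz_b <- as.vector(t(b))
  theirs <- bio3d::rmsd(xyz_a, xyz_b, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d prints at 3 decimals
})
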